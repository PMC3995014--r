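# rotation angle (degrees) of the linear part of an affine, ignoring scale
rotation_deg <- function(A) {
  L <- A[1:3, 1:3]
  R <- L %*% solve(chol(t(L) %*% L))   # polar decomposition rotation factor
  acos(pmin(pmax((sum(diag(R)) - 1) / 2, -1), 1)) * 180 / pi
}

test_that("affine self-registration recovers the identity", {
  ph <- fx_phantom()
  r <- register_affine(ph$image, ph$image)
  A <- r$transform$matrix
  expect_lt(max(abs(A[1:3, 4] + (A[1:3, 1:3] - diag(3)) %*% c(0, 0, 0))), 0.1)
  expect_lt(rotation_deg(A), 0.2)
  expect_true(r$converged)
})

test_that("affine registration recovers a known (4, -3, 2) mm translation", {
  ph <- fx_phantom()
  mov <- ph$image
  mov$affine[1:3, 4] <- mov$affine[1:3, 4] + c(4, -3, 2)
  r <- register_affine(mov, ph$image)
  ## map of the fixed-grid centre should be the centre + (4, -3, 2)
  A <- r$transform$matrix
  recovered <- A[1:3, 1:3] %*% c(0, 0, 0) + A[1:3, 4]
  expect_lt(max(abs(recovered - c(4, -3, 2))), 0.5)
})

test_that("disjoint world extents are a domain error", {
  a <- volume3d(array(rnorm(8^3), c(8, 8, 8)))
  b <- volume3d(array(rnorm(8^3), c(8, 8, 8)))
  b$affine[1:3, 4] <- b$affine[1:3, 4] + 500
  expect_error(register_affine(a, b), "disjoint")
})

test_that("transform composition behaves algebraically", {
  t1 <- affine_transform({A <- diag(4); A[1:3, 4] <- c(1, 2, 3); A})
  t2 <- affine_transform({A <- diag(4); A[1:3, 4] <- c(-4, 1, 0.5); A})
  id <- affine_transform(diag(4))
  expect_equal(compose(t1, id)$matrix, t1$matrix)
  expect_equal(compose(t1, t2)$matrix[1:3, 4], c(-3, 3, 3.5))
  ## inverse composes to identity
  R <- stepseg:::rot3(c(5, -3, 8)); A <- diag(4); A[1:3, 1:3] <- R; A[1:3, 4] <- c(2, -1, 4)
  t3 <- affine_transform(A)
  t3i <- affine_transform(solve(A))
  expect_lt(max(abs(compose(t3, t3i)$matrix - diag(4))), 1e-6)
})

test_that("composition of a field with an affine equals sequential application", {
  ph <- fx_clean_phantom()
  g <- ph$image
  disp <- array(0, c(dim(g$data), 3)); disp[, , , 1] <- 3; disp[, , , 2] <- -1
  fld <- stepseg:::deformation_field(disp, g)
  aft <- affine_transform({A <- diag(4); A[1:3, 4] <- c(-2, 4, 2); A})
  comp <- compose(fld, aft)
  seq1 <- apply_transform(apply_transform(g, aft, g, "linear"), fld, g, "linear")
  both <- apply_transform(g, comp, g, "linear")
  interior <- array(FALSE, dim(g$data)); interior[6:58, 6:58, 6:42] <- TRUE
  expect_lt(max(abs(seq1$data[interior] - both$data[interior])), 1e-6)
})

test_that("apply_transform handles identity, shifts and label modes", {
  ph <- fx_clean_phantom()
  lab <- stepseg:::side_mask(ph$label, "left")
  expect_identical(apply_transform(ph$image, NULL, ph$image, "linear")$data,
                   ph$image$data)
  ## pure 1-voxel integer translation in nearest mode: exact shifted mask
  t1 <- affine_transform({A <- diag(4); A[1:3, 4] <- c(2, 0, 0); A})  # 1 voxel at 2 mm
  sh <- apply_transform(lab, t1, lab, "nearest")
  d <- dim(lab$data)
  man <- array(0L, d); man[1:(d[1] - 1), , ] <- lab$data[2:d[1], , ]
  expect_identical(sh$data, man)
  ## linear label mode returns probabilities in [0, 1]
  t2 <- affine_transform({A <- diag(4); A[1:3, 4] <- c(0.7, -1.3, 0.4); A})
  pr <- apply_transform(lab, t2, lab, "linear")
  expect_true(all(pr$data >= 0 & pr$data <= 1))
  expect_false(inherits(pr, "label_volume"))
})

test_that("nonrigid self-registration stays at (numerically) zero displacement", {
  ph <- fx_subject()
  roi_vol <- ph$roi_vol
  r <- register_nonrigid(roi_vol, roi_vol, reg_preset("fine"))
  mg <- sqrt(r$transform$disp[, , , 1]^2 + r$transform$disp[, , , 2]^2 +
               r$transform$disp[, , , 3]^2)
  expect_lt(mean(mg) / mean(roi_vol$spacing), 0.2)
  expect_false(r$folding)
})

test_that("nonrigid registration recovers a 20% hippocampus size change", {
  s1 <- phantom_spec(seed = 11, jitter_trans = 0, jitter_rot = 0, noise_sd = 2)
  s2 <- s1; s2$atrophy <- c(left = 0.8, right = 0.8)
  p1 <- make_phantom(s1); p2 <- make_phantom(s2)
  idx <- which(p2$label$data == 1, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - 6, 1)
  hi <- pmin(apply(idx, 2, max) + 6, dim(p2$label$data))
  roi2 <- stepseg:::crop_volume(p2$image, lo, hi)
  roi1 <- stepseg:::crop_volume(p1$image, lo, hi)
  ra <- register_affine(roi1, roi2, list(levels = c(2, 1), maxit = c(300, 200)))
  rn <- register_nonrigid(roi1, roi2, reg_preset("fine"), initial = ra$transform)
  ## monotone acceptance: refined similarity at least the affine's
  w0 <- apply_transform(roi1, ra$transform, roi2, "linear")
  expect_gte(rn$similarity + 0.02, global_ncc(w0, roi2))
  pl <- apply_transform(stepseg:::side_mask(p1$label, "left"), rn$transform,
                        roi2, mode = "linear")
  m <- pl$data >= 0.5
  truth <- stepseg:::crop_volume(p2$label, lo, hi)$data == 1
  d <- 2 * sum(m & truth) / (sum(m) + sum(truth))
  expect_gte(d, 0.85)
  expect_false(rn$folding)
})

test_that("coarse preset uses strictly fewer control points than fine", {
  coarse <- reg_preset("coarse"); fine <- reg_preset("fine")
  n_ctrl <- function(lv, d = c(64, 64, 48)) {
    dl <- ceiling(d / lv$ds)
    prod(floor((dl - 1) / max(lv$spacing / lv$ds, 1)) + 4)
  }
  expect_lt(max(vapply(coarse$levels, n_ctrl, 0)),
            max(vapply(fine$levels, n_ctrl, 0)))
})

test_that("registration is deterministic", {
  ph <- fx_subject()
  r1 <- register_affine(ph$roi_vol, ph$roi_vol)
  r2 <- register_affine(ph$roi_vol, ph$roi_vol)
  expect_identical(r1$transform$matrix, r2$transform$matrix)
  n1 <- register_nonrigid(ph$roi_vol, ph$roi_vol, reg_preset("coarse"))
  n2 <- register_nonrigid(ph$roi_vol, ph$roi_vol, reg_preset("coarse"))
  expect_identical(n1$transform$disp, n2$transform$disp)
})

test_that("transforms serialize to text and NIfTI fields", {
  t1 <- affine_transform({A <- diag(4); A[1:3, 4] <- c(1, 2, 3); A})
  f <- tempfile(fileext = ".txt")
  write_transform(t1, f)
  expect_equal(matrix(scan(f, quiet = TRUE), 4, 4, byrow = TRUE), t1$matrix)
  ph <- fx_clean_phantom()
  disp <- array(rnorm(prod(dim(ph$image$data)) * 3, 0, 0.1),
                c(dim(ph$image$data), 3))
  fld <- stepseg:::deformation_field(disp, ph$image)
  f2 <- tempfile(fileext = ".nii.gz")
  write_transform(fld, f2)
  back <- RNifti::readNifti(f2)
  expect_equal(dim(back), dim(disp))
  expect_true(file.exists(paste0(f2, ".affine.txt")))
})
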