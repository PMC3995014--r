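test_that("mask volume follows slice-area x thickness, doubled in alternate mode", {
  m <- array(0L, c(20, 20, 10)); m[sample(length(m), 1000)] <- 1L
  lv <- label_volume(m, spacing = c(1, 1, 1))
  expect_equal(mask_volume(lv, "all"), 1.000)
  expect_equal(mask_volume(lv, "alternate"), 2.000)
  aniso <- label_volume(m, spacing = c(0.9375, 0.9375, 1.1))
  expect_equal(mask_volume(aniso, "all"), 0.9375^2 * 1.1 * 1000 / 1000,
               tolerance = 1e-10)
  expect_warning(v0 <- mask_volume(label_volume(array(0L, c(4, 4, 4)))), "empty")
  expect_equal(v0, 0)
})

test_that("alternate-mode volume doubles exactly on axially uniform slabs", {
  slab <- array(0L, c(12, 12, 10)); slab[4:9, 4:9, ] <- 1L
  lv <- label_volume(slab, spacing = c(2, 2, 2))
  measured <- slab; measured[, , seq(2, 10, 2)] <- 0L
  lv_alt <- label_volume(measured, grid = lv, labels = 1L)
  expect_identical(mask_volume(lv_alt, "alternate"), 2 * mask_volume(lv_alt, "all"))
  expect_identical(mask_volume(lv_alt, "alternate"), mask_volume(lv, "all"))
})

test_that("half-coverage contour rule is boundary inclusive", {
  ## rectangle exactly covering 3x3 voxel footprints -> 9 voxels
  grid <- label_volume(array(0L, c(8, 8, 3)), spacing = c(1, 1, 1))
  rect <- function(x0, x1, y0, y1)
    cbind(c(x0, x1, x1, x0, x0), c(y0, y0, y1, y1, y0))
  cs <- structure(list(slices = list(`2` = list(rect(1.5, 4.5, 1.5, 4.5))),
                       axis = 3L, dim = dim(grid$data), affine = grid$affine,
                       spacing = grid$spacing, alternate = FALSE),
                  class = "contour_set")
  m <- contours_to_mask(cs)
  expect_equal(sum(m$data), 9)
  expect_true(all(m$data[3:5, 3:5, 2] == 1))
  ## rectangle covering exactly half of one voxel: included (>= half rule)
  cs$slices <- list(`2` = list(rect(2.5, 3.0, 2.5, 3.5)))
  m2 <- contours_to_mask(cs)
  expect_equal(sum(m2$data), 1)
  expect_equal(m2$data[4, 4, 2], 1L)
  ## clearly under half: excluded
  cs$slices <- list(`2` = list(rect(2.5, 2.7, 2.5, 3.5)))
  expect_equal(sum(contours_to_mask(cs)$data), 0)
  ## open polygon rejected
  cs$slices <- list(`2` = list(cbind(c(0, 1), c(0, 1))))
  expect_error(contours_to_mask(cs), "polygon")
})

test_that("supersampling at 16x matches a 256x oracle on random polygons", {
  set.seed(8)
  grid <- label_volume(array(0L, c(32, 32, 3)), spacing = c(1, 1, 1))
  for (rep in 1:5) {
    ## random simple star-shaped polygon around a centre
    nv <- sample(5:9, 1)
    ang <- sort(runif(nv, 0, 2 * pi))
    rad <- runif(nv, 3, 10)
    ctr <- runif(2, 12, 20)
    poly <- cbind(ctr[1] + rad * cos(ang), ctr[2] + rad * sin(ang))
    poly <- rbind(poly, poly[1, ])
    cs <- structure(list(slices = list(`2` = list(poly)), axis = 3L,
                         dim = dim(grid$data), affine = grid$affine,
                         spacing = grid$spacing, alternate = FALSE),
                    class = "contour_set")
    m16 <- contours_to_mask(cs, sub = 4L)
    m256 <- contours_to_mask(cs, sub = 16L)
    diff_vox <- which(m16$data[, , 2] != m256$data[, , 2], arr.ind = TRUE)
    if (nrow(diff_vox) > 0) {
      ## any disagreement with the oracle must sit at voxels whose true
      ## coverage is within sampling resolution of the half threshold
      off <- (seq_len(16) - 8.5) / 16
      for (r in seq_len(nrow(diff_vox))) {
        cx <- diff_vox[r, 1] - 1; cy <- diff_vox[r, 2] - 1
        pts <- expand.grid(x = cx + off, y = cy + off)
        cov <- mean(stepseg:::pip_cpp(pts$x, pts$y, poly[, 1], poly[, 2],
                                      nrow(poly)))
        expect_gt(cov, 0.42); expect_lt(cov, 0.58)
      }
    }
    expect_lt(nrow(diff_vox), 4)
  }
})

test_that("normative fit recovers a constructed volume-ICV gradient", {
  set.seed(21)
  icv <- runif(50, 280, 380)
  vol <- 0.002 * icv + rnorm(50, 0, 1e-6) + 2
  nm <- fit_normative(vol, icv)
  expect_equal(nm$grad, 0.002, tolerance = 1e-3)
  expect_equal(unname(diff(nm$reference_range)), 2 * 1.96 * nm$sd_corrected)
  ## volumes independent of ICV: slope within 2 SE of zero
  vol2 <- rnorm(50, 3, 0.2)
  nm2 <- fit_normative(vol2, icv)
  se <- summary(lm(vol2 ~ icv))$coefficients[2, 2]
  expect_lt(abs(nm2$grad), 2 * se)
  expect_error(fit_normative(vol[1:2], icv[1:2]), "at least 3")
  expect_error(fit_normative(vol, rep(300, 50)), "variance")
})

test_that("ICV correction makes control volumes exactly ICV-orthogonal", {
  set.seed(4)
  icv <- runif(40, 280, 380)
  vol <- 1 + 0.004 * icv + rnorm(40, 0, 0.15)
  nm <- fit_normative(vol, icv)
  corr <- correct_volume(vol, icv, nm)
  expect_lt(abs(unname(coef(lm(corr ~ icv))[2])), 1e-10)
  ## special cases
  expect_equal(correct_volume(2.5, nm$mean_icv, nm), 2.5)
  nm0 <- nm; nm0$grad <- 0
  expect_equal(correct_volume(2.5, 999, nm0), 2.5)
})

test_that("classification flags sides below the lower reference limit", {
  set.seed(5)
  icv <- runif(30, 280, 380)
  vol <- 1 + 0.004 * icv + rnorm(30, 0, 0.1)
  nm <- fit_normative(vol, icv)
  m <- nm$mean_corrected; s <- nm$sd_corrected
  expect_equal(classify_volumes(m, m, nm)$class, "normal")
  expect_equal(classify_volumes(m, m, nm)$difference, 0)
  expect_equal(classify_volumes(m - 3 * s, m, nm)$class, "left atrophy")
  expect_equal(classify_volumes(m, m - 3 * s, nm)$class, "right atrophy")
  expect_equal(classify_volumes(m - 3 * s, m - 3 * s, nm)$class,
               "bilateral atrophy")
  ## invariance under a constant ICV shift of the control set
  nm_shift <- fit_normative(vol, icv + 50)
  corr1 <- correct_volume(vol[1], icv[1], nm)
  corr2 <- correct_volume(vol[1], icv[1] + 50, nm_shift)
  expect_equal(classify_volumes(corr1, corr1, nm)$class,
               classify_volumes(corr2, corr2, nm_shift)$class)
  expect_equal(corr1, corr2, tolerance = 1e-10)
})

test_that("whole-brain fusion estimates ICV within 5% of the analytic head", {
  bdb <- fixture("brain_db", function() make_brain_database(4, seed = 11))
  sub <- make_phantom(phantom_spec(seed = 321))
  est <- estimate_icv(sub$image, bdb, config = list(k_local = 3))
  expect_lt(abs(est$icv_cm3 - sub$icv_mm3 / 1000) / (sub$icv_mm3 / 1000), 0.05)
  ## deterministic across reruns
  est2 <- estimate_icv(sub$image, bdb, config = list(k_local = 3))
  expect_identical(est$icv_cm3, est2$icv_cm3)
})

test_that("estimated ICV is monotone in head size", {
  bdb <- fixture("brain_db", function() make_brain_database(4, seed = 11))
  sizes <- c(0.9, 1.0, 1.1)
  est <- vapply(sizes, function(hs) {
    sub <- make_phantom(phantom_spec(seed = 77, head_scale = hs))
    estimate_icv(sub$image, bdb, config = list(k_local = 3))$icv_cm3
  }, 0)
  expect_true(all(diff(est) > 0))
})
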