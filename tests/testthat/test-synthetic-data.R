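test_that("phantom generation is fully determined by its seed", {
  a <- make_phantom(phantom_spec(seed = 42))
  b <- make_phantom(phantom_spec(seed = 42))
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$label$data, b$label$data)
  ## changing only the noise seed leaves the label geometry untouched
  ps <- phantom_spec(seed = 42)
  c2 <- make_phantom(phantom_spec(seed = 43, pose_seed = ps$pose_seed))
  expect_identical(c2$label$data, a$label$data)
  expect_false(identical(c2$image$data, a$image$data))
})

test_that("atrophy scales rasterized label volume like an ellipsoid", {
  s1 <- phantom_spec(noise_sd = 0, bias_amp = 0, jitter_trans = 0,
                     jitter_rot = 0, atrophy = c(left = 1, right = 1))
  s2 <- s1; s2$atrophy <- c(left = 0.7, right = 0.7)
  n1 <- sum(make_phantom(s1)$label$data > 0)
  n2 <- sum(make_phantom(s2)$label$data > 0)
  expect_lt(abs(n2 / n1 - 0.7^3) / 0.7^3, 0.05)
})

test_that("noise- and bias-free phantoms are piecewise constant", {
  ph <- fx_clean_phantom()
  lev <- ph$spec$intensities
  expect_setequal(round(unique(as.vector(ph$image$data)), 6),
                  round(unname(lev), 6))
  ## true volumes recorded in metadata match a recount
  expect_equal(ph$volumes_mm3[["left"]],
               sum(ph$label$data == 1) * stepseg:::voxel_volume(ph$label))
})

test_that("structures that do not fit the grid are a domain error", {
  expect_error(make_phantom(phantom_spec(shape = c(24, 24, 16))), "exceeds")
  expect_error(phantom_spec(atrophy = c(left = 0.2, right = 1)), "atrophy")
})

test_that("template database honours the requested class mix exactly", {
  db <- fx_db()
  expect_identical(as.integer(table(db$meta$class)[c("bilateral", "left", "normal", "right")]),
                   rep(2L, 4))
  ## largest-remainder rounding on a non-divisible mix
  db2 <- make_template_database(
    5, atrophy_mix = c(left = 0.5, right = 0.3, bilateral = 0.2, normal = 0),
    seed = 3)
  tab <- table(factor(db2$meta$class, levels = c("left", "right", "bilateral", "normal")))
  expect_identical(as.integer(tab), c(3L, 1L, 1L, 0L))
  ## manifest truth equals recount, for every entry
  for (i in seq_along(db$entries)) {
    e <- db$entries[[i]]
    expect_equal(db$meta$vol_left_mm3[i],
                 sum(e$label$data == 1) * stepseg:::voxel_volume(e$label))
    expect_true(all(e$label$data %in% c(0L, 1L, 2L)))
    expect_true(same_grid(e$label, e$image))
  }
  expect_error(make_template_database(4, atrophy_mix = c(
    left = 0.5, right = 0.5, bilateral = 0.5, normal = 0)), "sum to 1")
  expect_error(make_template_database(1), "at least 2")
})

test_that("simulated raters realize their nominal error rates", {
  ph <- fx_phantom()
  truth <- stepseg:::side_mask(ph$label, "left")
  nfg <- sum(truth$data)
  expect_gt(nfg, 300)
  ## perfect rater reproduces the truth
  perfect <- simulate_rater(truth, rater_spec(1 - 1e-12, 1 - 1e-12, seed = 1))
  expect_identical(perfect$data, truth$data)
  ## p = 0.9, q = 0.99: observed rates within 3 binomial SEs
  r <- simulate_rater(truth, rater_spec(0.9, 0.99, seed = 5))
  obs_p <- sum(r$data[truth$data > 0]) / nfg
  nbg <- sum(truth$data == 0)
  obs_q <- 1 - sum(r$data[truth$data == 0]) / nbg
  expect_lt(abs(obs_p - 0.9), 3 * sqrt(0.9 * 0.1 / nfg))
  expect_lt(abs(obs_q - 0.99), 3 * sqrt(0.99 * 0.01 / nbg))
  ## different seeds, different realizations
  r2 <- simulate_rater(truth, rater_spec(0.9, 0.99, seed = 6))
  expect_false(identical(r$data, r2$data))
})

test_that("rater error rates converge to (p, q) by the law of large numbers", {
  ## prevalence-balanced toy truth with >= 1e4 voxels per class
  truth <- label_volume(array(rep(c(0L, 1L), each = 12^3), c(24, 12, 12)))
  for (seed in 1:3) {
    r <- simulate_rater(truth, rater_spec(0.85, 0.95, seed = seed))
    obs_p <- sum(r$data[truth$data > 0]) / sum(truth$data)
    obs_q <- 1 - sum(r$data[truth$data == 0]) / sum(truth$data == 0)
    expect_lt(abs(obs_p - 0.85), 3 * sqrt(0.85 * 0.15 / 12^3))
    expect_lt(abs(obs_q - 0.95), 3 * sqrt(0.95 * 0.05 / 12^3))
  }
})

test_that("contours trace slice boundaries at voxel-edge resolution", {
  ## a single 3x3 square: one rectilinear 12-edge closed polygon that
  ## encloses exactly its 9 voxel centres
  sq <- array(0L, c(8, 8, 3)); sq[3:5, 3:5, 2] <- 1L
  cs <- make_contours(label_volume(sq, spacing = c(1, 1, 1)))
  expect_length(cs$slices, 1)
  poly <- cs$slices[["2"]][[1]]
  expect_equal(nrow(poly) - 1, 12)    # closed: first vertex repeated
  inside <- stepseg:::pip_cpp(rep(0:7, 8), rep(0:7, each = 8),
                              poly[, 1], poly[, 2], nrow(poly))
  expect_equal(sum(inside), 9)
  expect_equal(which(matrix(inside, 8, 8), arr.ind = TRUE),
               which(sq[, , 2] > 0, arr.ind = TRUE), ignore_attr = TRUE)
})

test_that("alternate-slice contours keep odd slices only", {
  ph <- fx_phantom()
  lab <- stepseg:::side_mask(ph$label, "left")
  cs <- make_contours(lab, alternate = TRUE)
  expect_true(all(as.integer(names(cs$slices)) %% 2 == 1))
  full <- make_contours(lab)
  expect_true(length(cs$slices) < length(full$slices) ||
                all(as.integer(names(full$slices)) %% 2 == 1))
})

test_that("voxelizing traced contours recovers the mask exactly", {
  ph <- fx_phantom()
  for (side in c("left", "right")) {
    lab <- stepseg:::side_mask(ph$label, side)
    expect_identical(contours_to_mask(make_contours(lab))$data, lab$data)
  }
  ## alternate mode: exact on retained slices
  lab <- stepseg:::side_mask(ph$label, "left")
  cs <- make_contours(lab, alternate = TRUE)
  m <- contours_to_mask(cs)
  for (k in as.integer(names(cs$slices)))
    expect_identical(m$data[, , k], lab$data[, , k])
})

test_that("contour JSON serialization round-trips through world coordinates", {
  ph <- fx_phantom()
  lab <- stepseg:::side_mask(ph$label, "right")
  cs <- make_contours(lab)
  f <- tempfile(fileext = ".json")
  write_contours(cs, f)
  cs2 <- read_contours(f)
  expect_identical(contours_to_mask(cs2)$data, lab$data)
})
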