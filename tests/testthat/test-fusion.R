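test_that("LNCC is 1 for identical and intensity-rescaled images", {
  ph <- fx_phantom()
  l <- lncc(ph$image, ph$image, 2)
  expect_true(all(abs(l$data - 1) < 1e-6 | l$data == 0))
  expect_gt(mean(l$data > 0.999), 0.95)
  resc <- volume3d(3 * ph$image$data + 50, affine = ph$image$affine)
  l2 <- lncc(ph$image, resc, 2)
  expect_true(all(abs(l2$data - 1) < 1e-6 | l2$data == 0))
  expect_true(all(l$data >= -1 & l$data <= 1))
  expect_false(any(is.na(l$data)))
})

test_that("LNCC of independent noise is near zero", {
  set.seed(31)
  a <- volume3d(array(rnorm(64^3), c(64, 64, 64)))
  b <- volume3d(array(rnorm(64^3), c(64, 64, 64)))
  l <- lncc(a, b, 2)
  expect_lt(mean(abs(l$data)), 0.15)
})

test_that("local ranking selects exactly k templates per voxel", {
  set.seed(5)
  d <- c(16, 16, 16)
  maps <- lapply(1:6, function(i) volume3d(array(rnorm(prod(d)), d)))
  S <- local_rank_select(maps, 4)
  expect_true(all(rowSums(S) == 4))
  ## a strictly dominant template is always selected
  maps[[2]]$data[] <- 10
  S2 <- local_rank_select(maps, 1)
  expect_true(all(S2[, 2]))
  ## k equal to the template count selects everything
  S3 <- local_rank_select(maps, 6)
  expect_true(all(S3))
  expect_error(local_rank_select(maps, 7), "at least")
  ## ties broken by ascending template index
  tied <- matrix(1, 4, 3)
  St <- local_rank_select(tied, 2)
  expect_true(all(St[, 1] & St[, 2] & !St[, 3]))
})

test_that("unanimous templates drive consensus and parameters to the clamp", {
  d <- c(10, 10, 4)
  m <- array(0, d); m[3:6, 3:6, 2:3] <- 1
  D <- matrix(rep(as.vector(m), 4), ncol = 4)
  st <- staple_em(D, NULL, 0.5, fusion_config(k_local = 4, beta = 0))
  expect_identical(as.integer(st$W >= 0.5), as.integer(as.vector(m)))
  expect_true(all(st$p >= 0.999 - 1e-9))
  expect_true(all(st$q >= 0.999 - 1e-9))
})

test_that("STAPLE recovers simulated rater performance parameters", {
  ## 5 raters at p = 0.9, q = 0.98 on a phantom truth; EM run over the
  ## structure ROI, as in the pipeline. The phantom uses enlarged
  ## hippocampi (~2,000 foreground voxels) so that binomial noise in the
  ## realized rater rates stays well inside the recovery band.
  sp <- phantom_spec(shape = c(48, 48, 48), head_radius = 40,
                     hippo_radii = c(9.5, 11.5, 8.7), seed = 3)
  ph <- make_phantom(sp)
  truth <- stepseg:::side_mask(ph$label, "any")
  idx <- which(truth$data > 0, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - 5, 1)
  hi <- pmin(apply(idx, 2, max) + 5, dim(truth$data))
  tr <- stepseg:::crop_volume(truth, lo, hi)
  for (seed in 1:2) {
    raters <- lapply(1:5, function(i)
      simulate_rater(truth, rater_spec(0.9, 0.98, seed = 37 * seed + i)))
    D <- vapply(raters, function(r)
      as.double(stepseg:::crop_volume(r, lo, hi)$data), numeric(length(tr$data)))
    st <- staple_em(D, NULL, NULL, fusion_config(k_local = 5, beta = 0),
                    consensus_exclude = FALSE)
    expect_true(all(abs(st$p - 0.9) <= 0.03))
    expect_true(all(abs(st$q - 0.98) <= 0.01))
    ## fused beats every individual rater
    fdice <- dice(array(st$W >= 0.5, dim(tr$data)), tr$data)$dice
    rdice <- vapply(raters, function(r)
      dice(stepseg:::crop_volume(r, lo, hi), tr)$dice, 0)
    expect_gt(fdice, max(rdice))
    ## log-likelihood is non-decreasing at every EM iteration (beta = 0)
    expect_true(all(diff(st$loglik_trace) >= -1e-8))
  }
})

test_that("one EM pass with equal raters reduces to a vote-count monotone rule", {
  ## brute-force oracle on a 4 x 4 x 1 grid: enumerate all vote counts
  set.seed(9)
  nt <- 5
  D <- matrix(rbinom(16 * nt, 1, 0.5), 16, nt)
  cfg <- fusion_config(k_local = nt, beta = 0, max_iter = 1,
                       p_init = 0.9, q_init = 0.9)
  st <- staple_em(D, NULL, 0.5, cfg, consensus_exclude = FALSE)
  votes <- rowSums(D)
  ## with equal p = q and a flat prior, W must be a strictly increasing
  ## function of the vote count (brute-force check over all rows)
  for (v in sort(unique(votes))) {
    w_here <- st$W[votes == v]
    expect_lt(max(abs(w_here - w_here[1])), 1e-12)
  }
  w_by_vote <- vapply(sort(unique(votes)), function(v) st$W[votes == v][1], 0)
  expect_true(all(diff(w_by_vote) > 0))
  ## closed-form check: W = 1 / (1 + (q/(1-p))^k * ((1-q)/p)^(n-k)) at k votes
  for (v in sort(unique(votes))) {
    expected <- 1 / (1 + (0.9 / 0.1)^(nt - v) * (0.1 / 0.9)^v)
    expect_equal(st$W[votes == v][1], expected, tolerance = 1e-10)
  }
})

test_that("EM log-likelihood is monotone without the MRF", {
  refined <- fx_refined()
  s <- fx_subject()
  D <- vapply(refined, function(r) as.vector(r$prob$data),
              numeric(length(s$roi_vol$data)))
  lmaps <- lapply(refined, function(r) lncc(s$roi_vol, r$warped, 2))
  S <- local_rank_select(lmaps, 5)
  st <- staple_em(D, S, NULL, fusion_config(k_local = 5, beta = 0))
  expect_true(all(diff(st$loglik_trace) >= -1e-8))
})

test_that("the MRF prior follows neighbourhood agreement", {
  ## beta = 0: no spatial coupling, uniform 0.5
  W <- array(runif(4^3), c(4, 4, 4))
  expect_true(all(mrf_regularize(W, 0) == 0.5))
  ## uniform foreground: prior above 0.5 everywhere
  W1 <- array(1, c(4, 4, 4))
  expect_true(all(mrf_regularize(W1, 0.5) > 0.5))
  ## an isolated speck moves toward its neighbours under beta = 0.5
  d <- c(9, 9, 9)
  m <- array(0, d); m[3:7, 3:7, 3:7] <- 1; m[5, 5, 5] <- 0   # hole in a block
  pri <- mrf_regularize(m, 0.5)
  expect_gt(pri[5, 5, 5], 0.9)                                # pulled to 1
  m2 <- array(0, d); m2[5, 5, 5] <- 1                         # lone speck
  pri2 <- mrf_regularize(m2, 0.5)
  expect_lt(pri2[5, 5, 5], 0.1)                               # pushed to 0
})

test_that("MRF smoothing removes an isolated disagreement speck", {
  ## templates agree on a block; one template adds a distant speck that the
  ## beta = 0.5 run must suppress relative to beta = 0
  d <- c(12, 12, 6)
  block <- array(0, d); block[4:9, 4:9, 3:4] <- 1
  speck <- block; speck[11, 11, 5] <- 1
  D <- cbind(as.vector(speck), as.vector(speck),
             as.vector(block), as.vector(block), as.vector(block))
  st0 <- staple_em(D, NULL, NULL, fusion_config(k_local = 5, beta = 0), dims = d)
  st5 <- staple_em(D, NULL, NULL, fusion_config(k_local = 5, beta = 0.5), dims = d)
  i_speck <- which(as.vector(speck) == 1 & as.vector(block) == 0)
  expect_lt(st5$W[i_speck], st0$W[i_speck])
})

test_that("fusion with a single template returns that template's mask", {
  s <- fx_subject()
  refined <- fx_refined()
  one <- structure(refined[1], class = "refined_templates", side = "left")
  flat <- roi_crop(s$phantom$image, s$roi)
  flat$data[] <- 0.5
  ## identity limit: the posterior labeling under a flat prior and equal
  ## initial performance reproduces the template's own binarization
  f <- fuse(s$phantom$image, s$roi, one, prior = flat,
            config = fusion_config(k_local = 1, beta = 0, prior_weight = 1,
                                   max_iter = 1))
  m_direct <- stepseg:::largest_component(refined[[1]]$prob$data >= 0.5)
  got <- roi_crop(f$mask, s$roi)$data > 0
  expect_identical(got, m_direct)
})

test_that("fusion output is invariant to template ordering", {
  s <- fx_subject()
  refined <- fx_refined()
  f1 <- fuse(s$phantom$image, s$roi, refined,
             config = fusion_config(k_local = 5))
  perm <- rev(seq_along(refined))
  refp <- structure(refined[perm], class = "refined_templates", side = "left")
  f2 <- fuse(s$phantom$image, s$roi, refp,
             config = fusion_config(k_local = 5))
  expect_identical(f1$mask$data, f2$mask$data)
  expect_equal(f1$state$p[perm], f2$state$p, tolerance = 1e-9)
})

test_that("the closed loop on near-copy templates reaches Dice 0.9", {
  ## a db of near-copies of the subject (same geometry seed, fresh noise)
  sub <- fx_subject()
  base <- sub$phantom$spec
  copies <- lapply(1:6, function(i) {
    sp <- base; sp$seed <- stepseg:::child_seed(base$seed, 90 + i)
    ph <- make_phantom(sp)
    list(id = sprintf("cp%02d", i), image = ph$image, label = ph$label)
  })
  db <- structure(list(entries = copies,
                       meta = data.frame(id = vapply(copies, `[[`, "", "id"))),
                  class = "template_db")
  ranked <- select_templates(sub$roi_vol, db, side = "left", k_coarse = 6)
  refined <- refine_templates(ranked, sub$roi_vol, reg_preset("fine"),
                              min_templates = 5)
  f <- fuse(sub$phantom$image, sub$roi, refined,
            config = fusion_config(k_local = 5))
  expect_gte(dice_vs_truth(f$mask, sub$phantom), 0.90)
})
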