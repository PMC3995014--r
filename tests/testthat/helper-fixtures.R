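# Shared fixtures, built once per test run and cached. Everything is
# generated in code from seeds; there are no stored data files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

## fast phantom used in many tests (default desk-scale grid)
fx_phantom <- function() fixture("phantom", function() {
  make_phantom(phantom_spec(seed = 42))
})

## noiseless, jitter-free phantom for analytic checks
fx_clean_phantom <- function() fixture("clean", function() {
  make_phantom(phantom_spec(seed = 7, noise_sd = 0, bias_amp = 0,
                            jitter_trans = 0, jitter_rot = 0))
})

## small mixed-atrophy template database + its groupwise template
fx_db <- function() fixture("db", function() make_template_database(8, seed = 2))

fx_template <- function() fixture("template", function() {
  build_group_template(fx_db(), list(max_iter = 3))
})

## a subject with left atrophy, plus its propagated prior and left-side ROI
fx_subject <- function() fixture("subject", function() {
  sub <- make_phantom(phantom_spec(seed = 999, atrophy = c(left = 0.7, right = 1)))
  pri <- propagate_prior(fx_template(), sub$image)
  roi <- extract_roi(pri$left, 2, side = "left")
  list(phantom = sub, priors = pri, roi = roi,
       roi_vol = roi_crop(sub$image, roi))
})

## refined left-side templates for the fixture subject
fx_refined <- function() fixture("refined", function() {
  s <- fx_subject()
  proi <- roi_crop(s$priors$left, s$roi)
  W <- stepseg:::grid_world_coords(proi)
  ctr <- as.vector(colSums(W * as.vector(proi$data)) / sum(proi$data))
  ranked <- select_templates(s$roi_vol, fx_db(), side = "left", k_coarse = 8,
                             fixed_center = ctr)
  refine_templates(ranked, s$roi_vol, reg_preset("fine"), min_templates = 5)
})

## Dice of a binary array/mask against the fixture subject's left truth,
## evaluated on the full grid
dice_vs_truth <- function(mask, phantom, side = "left") {
  truth <- stepseg:::side_mask(phantom$label, side)
  dice(mask, truth)$dice
}

## study-scale database (20 mixed-atrophy templates) and its groupwise
## template, shared by the fusion-dominance and atrophy-robustness checks
fx_db20 <- function() fixture("db20", function() {
  db <- make_template_database(20, seed = 101)
  gt <- build_group_template(db, list(max_iter = 3))
  list(db = db, template = gt)
})

## run the full left-side pipeline on one subject against fx_db20,
## returning fused / majority / best-ranked-template Dice
segment_and_score <- function(image, label, k_local = 15, beta = 0.5) {
  x <- fx_db20()
  pri <- propagate_prior(x$template, image)
  roi <- extract_roi(pri$left, 2, "left")
  sroi <- roi_crop(image, roi)
  proi <- roi_crop(pri$left, roi)
  W <- stepseg:::grid_world_coords(proi)
  ctr <- as.vector(colSums(W * as.vector(proi$data)) / sum(proi$data))
  ranked <- suppressWarnings(
    select_templates(sroi, x$db, "left", k_coarse = 75, fixed_center = ctr))
  refined <- refine_templates(ranked, sroi, reg_preset("fine"),
                              min_templates = k_local)
  f <- fuse(image, roi, refined, prior = proi,
            config = fusion_config(k_local = k_local, beta = beta))
  truth <- stepseg:::side_mask(label, "left")
  embed <- function(m) label_volume(stepseg:::roi_embed(as.integer(m), roi, image),
                                    grid = image, labels = 1L)
  best_idx <- which.max(vapply(refined, `[[`, 0, "fine_ncc"))
  best <- embed(stepseg:::largest_component(refined[[best_idx]]$prob$data >= 0.5))
  list(fused = dice(f$mask, truth)$dice,
       majority = dice(fuse_majority(image, roi, refined), truth)$dice,
       best_single = dice(best, truth)$dice,
       state = f$state, refined = refined, roi = roi, prior = proi)
}

## tiny on-disk database for end-to-end determinism checks
fx_dbdir <- function() fixture("dbdir", function() {
  d <- file.path(tempfile(), "accept_db")
  pipeline_build_db(d, pipeline_config(n_templates = 2, seed = 9,
                                       template_max_iter = 2))
  d
})
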