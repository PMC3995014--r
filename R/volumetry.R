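## Volumetry: mask volumes (with the alternate-slice doubling rule),
## intracranial volume by whole-brain multi-atlas fusion, the ICV
## regression correction, normative reference ranges, and sum/difference
## volume classification.

#' Volume of a binary mask in cm^3
#'
#' Sum of per-slice cross-sectional areas times slice thickness. In
#' `"alternate"` mode — masks segmented on every other slice only — the
#' result is doubled to account for the unmeasured slices.
#'
#' @param mask Binary [label_volume].
#' @param slice_mode `"all"` or `"alternate"`.
#' @return Volume in cm^3.
#' @export
mask_volume <- function(mask, slice_mode = c("all", "alternate")) {
  slice_mode <- match.arg(slice_mode)
  n <- sum(mask$data > 0)
  if (n == 0) {
    warning("empty mask: volume 0")
    return(0)
  }
  v <- n * voxel_volume(mask) / 1000
  if (slice_mode == "alternate") v <- 2 * v
  v
}

#' Estimate intracranial volume by whole-brain fusion
#'
#' Applies the same selection-and-fusion algorithm used for the
#' hippocampus with a template database of whole-brain masks: every brain
#' template is registered to the subject, the most similar are kept, and
#' their propagated brain masks are fused; the ICV is the fused mask
#' volume.
#'
#' @param subject [volume3d].
#' @param brain_db A `template_db` whose labels are whole-brain masks
#'   (see [make_brain_database]).
#' @param config List: `k_coarse` (default all), `k_local` (default 5),
#'   `fine` preset (default `"coarse"`, brains are easy), fusion overrides.
#' @return List `icv_cm3`, `mask`, `state`.
#' @export
estimate_icv <- function(subject, brain_db, config = list()) {
  cfg <- modifyList(list(k_coarse = length(brain_db$entries), k_local = 5,
                         fine = reg_preset("coarse"), beta = 0.5), config)
  roi <- structure(list(lo = c(1L, 1L, 1L), hi = dim(subject$data),
                        margin = 0L, side = "brain",
                        grid_dim = dim(subject$data)), class = "roi")
  ranked <- select_templates(subject, brain_db, side = "brain",
                             k_coarse = cfg$k_coarse,
                             config = list(levels = c(2, 1)))
  refined <- refine_templates(ranked, subject, cfg$fine,
                              min_templates = cfg$k_local)
  fc <- fusion_config(k_local = cfg$k_local, beta = cfg$beta)
  fused <- fuse(subject, roi, refined, prior = NULL, config = fc)
  list(icv_cm3 = mask_volume(fused$mask), mask = fused$mask,
       state = fused$state)
}

#' Brain-mask template database
#'
#' Companion to [make_template_database]: the same phantom generator, but
#' each entry's label is the whole-head mask (the intracranial volume
#' proxy), for use with [estimate_icv].
#'
#' @inheritParams make_template_database
#' @export
make_brain_database <- function(n, base_spec = phantom_spec(),
                                head_scale_sd = 0.04, seed = 1) {
  if (n < 2) stop("a template database needs at least 2 entries")
  entries <- vector("list", n)
  meta <- vector("list", n)
  lev <- base_spec$intensities
  for (i in seq_len(n)) {
    si <- child_seed(seed, 500 + i)
    hs <- with_seed(si, max(0.85, min(1.15, 1 + rnorm(1, 0, head_scale_sd))))
    sp <- base_spec
    sp$head_scale <- hs
    sp$seed <- child_seed(si, 3)
    sp$pose_seed <- child_seed(si, 4)
    ph <- make_phantom(sp)
    thr <- (lev[["background"]] + lev[["csf"]]) / 2
    head <- array(as.integer(ph$image$data > thr), dim(ph$image$data))
    id <- sprintf("brn%03d", i)
    entries[[i]] <- list(id = id, image = ph$image,
                         label = label_volume(head, grid = ph$image,
                                              labels = 1L))
    meta[[i]] <- data.frame(id = id, class = "brain",
                            vol_left_mm3 = NA_real_, vol_right_mm3 = NA_real_,
                            icv_mm3 = ph$icv_mm3, seed = sp$seed)
  }
  structure(list(entries = entries, meta = do.call(rbind, meta)),
            class = "template_db")
}

#' Fit a normative hippocampal-volume model
#'
#' OLS regression of hippocampal volume on intracranial volume over a
#' control set; stores the slope (`grad`), the control mean ICV, and the
#' mean/SD of the ICV-corrected control volumes, from which the reference
#' range `mean +/- 1.96 SD` is derived.
#'
#' @param hippo_cm3,icv_cm3 Control volumes (cm^3), one pair per
#'   hippocampus.
#' @return `normative_model`: `grad`, `mean_icv`, `mean_corrected`,
#'   `sd_corrected`, `reference_range`, `n`.
#' @export
fit_normative <- function(hippo_cm3, icv_cm3) {
  stopifnot(length(hippo_cm3) == length(icv_cm3))
  n <- length(hippo_cm3)
  if (n < 3) stop("need at least 3 control hippocampi")
  if (sd(icv_cm3) < 1e-12) stop("ICV variance is zero; cannot regress")
  fit <- lm(hippo_cm3 ~ icv_cm3)
  grad <- unname(coef(fit)[2])
  mean_icv <- mean(icv_cm3)
  corrected <- hippo_cm3 - grad * (icv_cm3 - mean_icv)
  m <- mean(corrected); s <- sd(corrected)
  structure(list(grad = grad, mean_icv = mean_icv,
                 mean_corrected = m, sd_corrected = s,
                 reference_range = c(lower = m - 1.96 * s,
                                     upper = m + 1.96 * s),
                 n = n),
            class = "normative_model")
}

#' @export
print.normative_model <- function(x, ...) {
  cat(sprintf("<normative_model> n = %d controls\n", x$n))
  cat(sprintf("  Grad %.4f cm^3 per cm^3 ICV (mean ICV %.1f cm^3)\n",
              x$grad, x$mean_icv))
  cat(sprintf("  corrected volumes %.3f (SD %.3f) cm^3; reference range %.2f-%.2f cm^3\n",
              x$mean_corrected, x$sd_corrected,
              x$reference_range[1], x$reference_range[2]))
  invisible(x)
}

#' Correct a hippocampal volume for head size
#'
#' `corrected = raw - Grad * (ICV - mean ICV)`: removes the
#' regression-predicted dependence on intracranial volume, so corrected
#' control volumes are exactly uncorrelated with ICV.
#'
#' @param raw_cm3 Raw volume (cm^3).
#' @param icv_cm3 The subject's intracranial volume (cm^3).
#' @param model A [fit_normative] model.
#' @export
correct_volume <- function(raw_cm3, icv_cm3, model) {
  stopifnot(inherits(model, "normative_model"))
  raw_cm3 - model$grad * (icv_cm3 - model$mean_icv)
}

#' Classify a subject on the corrected-volume plane
#'
#' Each side is flagged atrophic when its corrected volume falls below
#' `mean - 1.96 SD` of the corrected control volumes (the lower reference
#' limit). Also returns the (sum, left - right) coordinates used for the
#' sum-versus-difference scatter. This is a volumetric surrogate for a
#' radiological reading, not a clinical classification.
#'
#' @param left_corr,right_corr Corrected volumes (cm^3).
#' @param model A [fit_normative] model.
#' @return List: `class` (one of `"normal"`, `"left atrophy"`,
#'   `"right atrophy"`, `"bilateral atrophy"`), `sum`, `difference`,
#'   `cutoff`.
#' @export
classify_volumes <- function(left_corr, right_corr, model) {
  stopifnot(inherits(model, "normative_model"))
  cutoff <- model$mean_corrected - 1.96 * model$sd_corrected
  la <- left_corr < cutoff; ra <- right_corr < cutoff
  cls <- if (la && ra) "bilateral atrophy" else if (la) "left atrophy"
         else if (ra) "right atrophy" else "normal"
  list(class = cls, sum = left_corr + right_corr,
       difference = left_corr - right_corr, cutoff = unname(cutoff))
}

#' Assemble a volume report row
#'
#' @param subject_id,side Identifiers.
#' @param mask Binary [label_volume].
#' @param icv_cm3 Intracranial volume (cm^3), optional.
#' @param model Normative model, optional (enables corrected volume).
#' @param method `"manual"` or `"automated"`.
#' @param slice_mode `"all"` or `"alternate"`.
#' @return One-row data frame (volumes in cm^3, 3 decimals).
#' @export
volume_report <- function(subject_id, side, mask, icv_cm3 = NA_real_,
                          model = NULL, method = "automated",
                          slice_mode = "all") {
  raw <- mask_volume(mask, slice_mode)
  corr <- if (!is.null(model) && is.finite(icv_cm3))
    correct_volume(raw, icv_cm3, model) else NA_real_
  data.frame(subject = subject_id, side = side,
             raw_cm3 = round(raw, 3), corrected_cm3 = round(corr, 3),
             icv_cm3 = round(icv_cm3, 3), method = method,
             slice_mode = slice_mode)
}
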