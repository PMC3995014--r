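## Template selection: extract the hippocampal region-of-interest from the
## propagated prior, coarsely (affinely) register every template to it,
## keep the k_coarse most similar by global NCC, then refine those with
## nonrigid registration and carry their labels across as probability maps.

#' Extract a region-of-interest box from a propagated prior
#'
#' Tight bounding box of the prior's 0.5-level set, dilated by a margin and
#' clipped to the grid.
#'
#' @param prior Probability map ([volume3d]) on the subject grid.
#' @param margin_voxels Dilation margin in voxels (default 2). Small
#'   margins keep the registration and similarity metrics focused on the
#'   structure; large margins admit distractor anatomy (ventricle, brain
#'   edge) that dominates the NCC and degrades small-structure alignment.
#' @param side `"left"`, `"right"` or `"brain"` (bookkeeping only).
#' @return `roi` object: `lo`, `hi` (1-based inclusive index ranges),
#'   `margin`, `side`.
#' @export
extract_roi <- function(prior, margin_voxels = 2, side = "left") {
  lev <- prior$data >= 0.5
  if (!any(lev))
    stop("empty prior: no voxel reaches probability 0.5 ",
         "(upstream registration failure)")
  idx <- which(lev, arr.ind = TRUE)
  d <- dim(prior$data)
  lo <- pmax(apply(idx, 2, min) - margin_voxels, 1L)
  hi <- pmin(apply(idx, 2, max) + margin_voxels, d)
  structure(list(lo = as.integer(lo), hi = as.integer(hi),
                 margin = margin_voxels, side = side, grid_dim = d),
            class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> %s side, [%s] to [%s] (margin %d)\n", x$side,
              paste(x$lo, collapse = ","), paste(x$hi, collapse = ","),
              x$margin))
  invisible(x)
}

#' Crop a volume to an ROI
#' @param vol Volume on the grid the ROI was defined on.
#' @param roi An [extract_roi] object.
#' @export
roi_crop <- function(vol, roi) crop_volume(vol, roi$lo, roi$hi)

## re-embed an ROI-level array into the full grid (fill elsewhere)
roi_embed <- function(data_roi, roi, full_grid, fill = 0L) {
  out <- array(fill, dim(full_grid$data))
  out[roi$lo[1]:roi$hi[1], roi$lo[2]:roi$hi[2], roi$lo[3]:roi$hi[3]] <- data_roi
  out
}

#' Global normalized cross-correlation
#'
#' Pearson correlation of intensities over (optionally masked) voxels.
#' A constant image within the mask is uninformative: the score is defined
#' as 0 and a warning is raised rather than an error, so one degenerate
#' template cannot abort selection.
#'
#' @param a,b [volume3d]s on the same grid.
#' @param mask Optional logical array on the same grid.
#' @return Scalar in \[-1, 1\].
#' @export
global_ncc <- function(a, b, mask = NULL) {
  if (!same_grid(a, b)) stop("global_ncc requires volumes on the same grid")
  av <- as.vector(a$data); bv <- as.vector(b$data)
  if (!is.null(mask)) {
    m <- as.vector(mask)
    if (!any(m)) stop("empty mask")
    av <- av[m]; bv <- bv[m]
  }
  if (sd(av) < 1e-12 || sd(bv) < 1e-12) {
    warning("constant image within mask; NCC undefined, returning 0")
    return(0)
  }
  ncc_vec(av, bv)
}

## brain mask used as NCC support: voxels clearly above background in the
## subject ROI (background-dominant boxes would otherwise swamp the score)
roi_brain_mask <- function(roi_vol) {
  thr <- 0.2 * quantile(roi_vol$data, 0.99)
  m <- roi_vol$data > thr
  if (sum(m) < 32) m[] <- TRUE
  m
}

## crop a template entry around its own label (side) with margin, so
## coarse registration starts from roughly corresponding content
entry_crop <- function(entry, side, margin = 8) {
  if (side == "brain") return(entry)
  lab <- side_mask(entry$label, side)
  idx <- which(lab$data > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  d <- dim(entry$image$data)
  lo <- pmax(apply(idx, 2, min) - margin, 1L)
  hi <- pmin(apply(idx, 2, max) + margin, d)
  list(id = entry$id,
       image = crop_volume(entry$image, lo, hi),
       label = crop_volume(entry$label, lo, hi))
}

#' Rank templates against a subject ROI by coarse registration + NCC
#'
#' Every template is cropped around its own hippocampus label, affinely
#' registered to the subject ROI, and scored by global NCC over the ROI
#' brain mask. The `k_coarse` best (descending NCC, ties broken by
#' ascending template id) are returned. Failed registrations are excluded
#' with a message.
#'
#' @param subject_roi [volume3d], the cropped subject ROI.
#' @param db Template database.
#' @param side `"left"`, `"right"` or `"brain"`.
#' @param k_coarse Number of templates to keep (default 75); if the
#'   database is smaller, all are kept with a warning.
#' @param fixed_center Optional world-mm coordinate of the expected
#'   structure centre in the ROI (e.g. the propagated prior's centroid);
#'   each template is then initialized by aligning its own label centroid
#'   to it, which is more robust than intensity centre-of-mass alignment.
#' @param config Affine registration config overrides.
#' @return `ranked_templates`: data frame `ranking` (id, ncc, included)
#'   plus per-template transforms and cropped entries.
#' @export
select_templates <- function(subject_roi, db, side = "left", k_coarse = 75,
                             fixed_center = NULL, config = list()) {
  stopifnot(inherits(db, "template_db"))
  n <- length(db$entries)
  if (n < k_coarse) {
    warning("database has ", n, " templates; k_coarse = ", k_coarse,
            " reduced to ", n)
    k_coarse <- n
  }
  mask <- roi_brain_mask(subject_roi)
  acfg <- modifyList(list(levels = c(2, 1), maxit = c(300, 200)), config)
  cand <- list()
  for (e in db$entries) {
    ec <- entry_crop(e, side)
    if (is.null(ec)) { message("template ", e$id, " has no ", side,
                               " label; excluded"); next }
    ecfg <- acfg
    if (!is.null(fixed_center) && side != "brain") {
      lab <- side_mask(ec$label, side)
      Wm <- grid_world_coords(lab)
      ecfg$c_moving <- as.vector(colSums(Wm * as.vector(lab$data > 0)) /
                                   sum(lab$data > 0))
      ecfg$c_fixed <- fixed_center
    }
    res <- tryCatch(register_affine(ec$image, subject_roi, ecfg),
                    error = function(err) NULL)
    if (is.null(res)) { message("template ", e$id,
                                " failed coarse registration; excluded"); next }
    warped <- apply_transform(ec$image, res$transform, subject_roi, "linear")
    score <- suppressWarnings(global_ncc(warped, subject_roi, mask))
    cand[[length(cand) + 1]] <- list(id = ec$id, ncc = score,
                                     transform = res$transform, entry = ec)
  }
  if (!length(cand)) stop("no template survived coarse registration")
  ids <- vapply(cand, `[[`, "", "id")
  nccs <- vapply(cand, `[[`, 0, "ncc")
  ord <- order(-nccs, ids)
  keep <- ord[seq_len(min(k_coarse, length(ord)))]
  ranking <- data.frame(id = ids[ord], coarse_ncc = nccs[ord],
                        included = seq_along(ord) %in% seq_len(length(keep)))
  structure(list(ranking = ranking, selected = cand[keep],
                 side = side, mask = mask),
            class = "ranked_templates")
}

#' @export
print.ranked_templates <- function(x, ...) {
  cat(sprintf("<ranked_templates> %s side, %d selected of %d registered\n",
              x$side, length(x$selected), nrow(x$ranking)))
  print(head(x$ranking, 5))
  invisible(x)
}

#' Finely register selected templates and propagate their labels
#'
#' Nonrigid refinement of each coarse transform, then label propagation to
#' the ROI grid as continuous probability maps. Per-template failures are
#' excluded with a message; fewer than `min_templates` survivors is a
#' pipeline error (local fusion needs at least that many).
#'
#' @param ranked A [select_templates] result.
#' @param subject_roi The subject ROI volume the ranking was made against.
#' @param config A [reg_preset] (default `"fine"`).
#' @param min_templates Minimum surviving templates (default 15, the local
#'   fusion count).
#' @return `refined_templates`: list of per-template records (id,
#'   coarse/fine NCC, transform, `prob` label probability map).
#' @export
refine_templates <- function(ranked, subject_roi, config = reg_preset("fine"),
                             min_templates = 15) {
  stopifnot(inherits(ranked, "ranked_templates"))
  out <- list()
  for (tc in ranked$selected) {
    res <- tryCatch(
      register_nonrigid(tc$entry$image, subject_roi, config,
                        initial = tc$transform),
      error = function(err) NULL)
    if (is.null(res)) {
      message("template ", tc$id, " failed fine registration; excluded")
      next
    }
    warped <- apply_transform(tc$entry$image, res$transform, subject_roi, "linear")
    fine_ncc <- suppressWarnings(global_ncc(warped, subject_roi, ranked$mask))
    lab <- if (ranked$side == "brain") side_mask(tc$entry$label, "any")
           else side_mask(tc$entry$label, ranked$side)
    prob <- apply_transform(lab, res$transform, subject_roi, mode = "linear")
    prob$data[] <- pmin(pmax(prob$data, 0), 1)
    out[[length(out) + 1]] <- list(id = tc$id, coarse_ncc = tc$ncc,
                                   fine_ncc = fine_ncc,
                                   transform = res$transform, prob = prob,
                                   warped = warped)
  }
  if (length(out) < min_templates)
    stop("only ", length(out), " templates survived fine registration; ",
         "at least ", min_templates, " are required for local fusion")
  structure(out, class = "refined_templates", side = ranked$side)
}
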