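## Groupwise average template: iterative register-and-average. The first
## iteration aligns every entry to an arbitrary reference (first id in sort
## order, for reproducibility) affinely; later iterations register everyone
## nonrigidly to the evolving average. The same transforms are applied to
## the label maps, whose average is the spatial prior used to localize the
## hippocampus on new subjects.

#' Build a groupwise anatomical template and label prior
#'
#' @param db A [make_template_database] object (entries on compatible
#'   grids).
#' @param config List: `max_iter` (default 5), `tol` (relative mean
#'   absolute intensity change between successive averages, default 0.01),
#'   `nonrigid` preset for iterations >= 2 (default [reg_preset]
#'   `"coarse"`), `affine` config for iteration 1.
#' @return `group_template`: `mean` ([volume3d]), `prior` (list of
#'   left/right probability maps), `transforms` (per entry, template grid
#'   -> entry), `iterations`, `trace` (per-iteration change), `converged`.
#' @export
build_group_template <- function(db, config = list()) {
  if (!inherits(db, "template_db") || length(db$entries) < 2)
    stop("db must be a template_db with at least 2 entries")
  cfg <- modifyList(list(max_iter = 5, tol = 0.01,
                         nonrigid = reg_preset("coarse"), affine = list()),
                    config)
  ids <- vapply(db$entries, `[[`, "", "id")
  ord <- order(ids)
  entries <- db$entries[ord]
  ref <- entries[[1]]$image
  grid <- ref

  resample_all <- function(transforms) {
    imgs <- mapply(function(e, t) apply_transform(e$image, t, grid, "linear")$data,
                   entries, transforms, SIMPLIFY = FALSE)
    avg <- Reduce(`+`, imgs) / length(imgs)
    pri <- lapply(c("left", "right"), function(s) {
      ps <- mapply(function(e, t)
        apply_transform(side_mask(e$label, s), t, grid, "linear")$data,
        entries, transforms, SIMPLIFY = FALSE)
      Reduce(`+`, ps) / length(ps)
    })
    list(avg = volume3d(avg, affine = grid$affine),
         prior = list(left = volume3d(pri[[1]], affine = grid$affine),
                      right = volume3d(pri[[2]], affine = grid$affine)))
  }

  # first-order debiasing: compose each subject map with the inverse of
  # the mean displacement, so the template geometry tracks the group mean
  # rather than the arbitrary reference
  debias <- function(transforms) {
    W <- grid_world_coords(grid)
    mdisp <- 0
    for (t in transforms) mdisp <- mdisp + (transform_points(t, W) - W)
    mdisp <- mdisp / length(transforms)
    corr <- deformation_field(array(-mdisp, c(dim(grid$data), 3)), grid)
    lapply(transforms, function(t) compose(corr, t, grid = grid))
  }

  # iteration 1: affine to the reference, then voxelwise mean
  aff <- lapply(entries, function(e) register_affine(e$image, ref, cfg$affine))
  transforms <- debias(lapply(aff, `[[`, "transform"))
  cur <- resample_all(transforms)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 1L
  while (iter < cfg$max_iter) {
    iter <- iter + 1L
    # iterations >= 2: nonrigid to the current average
    regs <- mapply(function(e, a)
      register_nonrigid(e$image, cur$avg, cfg$nonrigid, initial = a$transform),
      entries, aff, SIMPLIFY = FALSE)
    transforms <- debias(lapply(regs, `[[`, "transform"))
    nxt <- resample_all(transforms)
    brain <- cur$avg$data > 0.2 * max(cur$avg$data)
    delta <- mean(abs(nxt$avg$data[brain] - cur$avg$data[brain])) /
      mean(abs(cur$avg$data[brain]))
    trace <- c(trace, delta)
    cur <- nxt
    if (delta < cfg$tol) { converged <- TRUE; break }
  }
  structure(list(mean = cur$avg, prior = cur$prior,
                 transforms = stats::setNames(transforms, ids[ord]),
                 iterations = iter, trace = trace, converged = converged,
                 ids = ids[ord]),
            class = "group_template")
}

#' @export
print.group_template <- function(x, ...) {
  cat(sprintf("<group_template> %d subjects, %d iterations%s\n",
              length(x$ids), x$iterations,
              if (x$converged) ", converged" else " (iteration cap reached)"))
  if (length(x$trace))
    cat("  change trace:", paste(signif(x$trace, 3), collapse = " "), "\n")
  invisible(x)
}

#' Propagate the group label prior to a subject scan
#'
#' Registers the template mean to the subject (affine + coarse nonrigid)
#' and carries the left/right label priors along, giving the approximate
#' hippocampus location on the subject grid.
#'
#' @param template A `group_template`.
#' @param subject [volume3d].
#' @param config List with `nonrigid` preset (default `"coarse"`) and
#'   `affine` config.
#' @return List `left`, `right` (probability maps on the subject grid, in
#'   \[0,1\]) and `transform` (subject grid -> template space).
#' @export
propagate_prior <- function(template, subject, config = list()) {
  cfg <- modifyList(list(nonrigid = reg_preset("coarse"), affine = list()),
                    config)
  ra <- register_affine(template$mean, subject, cfg$affine)
  rn <- register_nonrigid(template$mean, subject, cfg$nonrigid,
                          initial = ra$transform)
  pl <- apply_transform(template$prior$left, rn$transform, subject, "linear")
  pr <- apply_transform(template$prior$right, rn$transform, subject, "linear")
  clip01 <- function(v) { v$data[] <- pmin(pmax(v$data, 0), 1); v }
  list(left = clip01(pl), right = clip01(pr), transform = rn$transform,
       similarity = rn$similarity)
}
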