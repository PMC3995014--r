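## Self-contained registration engine: multi-resolution Nelder-Mead
## optimization of normalized cross-correlation for affine alignment, and
## gradient ascent on NCC with a bending-energy penalty over a cubic
## B-spline control lattice for free-form nonrigid refinement. Transforms
## map fixed-grid world coordinates to moving-image world coordinates (the
## resampling / pull-back convention).

#' Affine transform (world-to-world)
#' @param matrix 4x4 invertible matrix mapping fixed-world to moving-world mm.
#' @export
affine_transform <- function(matrix = diag(4)) {
  matrix <- unclass(matrix)[1:4, 1:4]
  if (abs(det(matrix)) < 1e-12) stop("affine transform is singular")
  structure(list(matrix = matrix), class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform>\n"); print(signif(x$matrix, 5)); invisible(x)
}

## deformation: phi(x) = A %*% (x + u(x)), u dense mm displacements stored
## on `grid` (a volume3d skeleton), A the folded-in initial affine
deformation_field <- function(disp, grid, affine = diag(4),
                              control_spacing = NA_real_) {
  stopifnot(length(dim(disp)) == 4, dim(disp)[4] == 3)
  if (any(!is.finite(disp))) stop("deformation field contains non-finite values")
  structure(list(disp = disp, grid = grid[c("affine", "spacing")],
                 dim = dim(disp)[1:3], affine = affine,
                 control_spacing = control_spacing),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  mg <- sqrt(x$disp[, , , 1]^2 + x$disp[, , , 2]^2 + x$disp[, , , 3]^2)
  cat(sprintf("<deformation_field> grid %s, mean|u| %.3f mm, max|u| %.3f mm\n",
              paste(x$dim, collapse = "x"), mean(mg), max(mg)))
  invisible(x)
}

## evaluate phi at world points (n x 3) -> moving-world points
transform_points <- function(t, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  if (inherits(t, "affine_transform")) {
    sweep(xyz %*% t(t$matrix[1:3, 1:3]), 2, t$matrix[1:3, 4], `+`)
  } else if (inherits(t, "deformation_field")) {
    gaff <- t$grid$affine
    v <- world_to_voxel(gaff, xyz)
    u <- vapply(1:3, function(c)
      interp3_cpp(as.double(t$disp[, , , c]), t$dim,
                  v[, 1], v[, 2], v[, 3], 0L), numeric(nrow(xyz)))
    y <- xyz + matrix(u, ncol = 3)
    sweep(y %*% t(t$affine[1:3, 1:3]), 2, t$affine[1:3, 4], `+`)
  } else stop("unknown transform class")
}

#' Apply a transform to a volume
#'
#' Resamples `vol` onto `target_grid` through the transform (pull-back:
#' output voxel x takes the moving-image value at phi(x)). Intensities are
#' interpolated linearly. Labels: `mode = "nearest"` gives a hard mask;
#' `mode = "linear"` interpolates the per-side indicator and returns a
#' continuous probability map in \[0, 1\] (kept continuous for fusion).
#'
#' @param vol Moving [volume3d] or [label_volume].
#' @param t An `affine_transform` or `deformation_field` (or `NULL` for
#'   identity).
#' @param target_grid Grid of the output (defaults to `vol`'s own grid).
#' @param mode `"linear"` or `"nearest"`.
#' @return Volume on `target_grid`; linear-mode labels come back as
#'   [volume3d] probability maps.
#' @export
apply_transform <- function(vol, t, target_grid = vol, mode = NULL) {
  if (is.null(mode)) mode <- if (inherits(vol, "label_volume")) "nearest" else "linear"
  mode <- match.arg(mode, c("linear", "nearest"))
  if (is.null(t)) t <- affine_transform(diag(4))
  w <- grid_world_coords(target_grid)
  y <- transform_points(t, w)
  v <- world_to_voxel(vol$affine, y)
  is_label <- inherits(vol, "label_volume")
  src <- if (is_label && mode == "linear") as.double(vol$data > 0) else as.double(vol$data)
  out <- interp3_cpp(src, dim(vol$data), v[, 1], v[, 2], v[, 3],
                     as.integer(mode == "nearest"))
  dim(out) <- dim(target_grid$data)
  if (is_label && mode == "nearest")
    label_volume(out, grid = target_grid, labels = vol$labels)
  else volume3d(out, affine = target_grid$affine)
}

#' Compose two transforms
#'
#' `compose(t1, t2)` applies `t1` first: phi(x) = phi_t2(phi_t1(x)), so
#' resampling through the composition equals resampling through `t2` then
#' `t1` sequentially (within interpolation error for dense fields).
#'
#' @param t1,t2 Transforms.
#' @param grid Grid on which a dense composed field is sampled when either
#'   argument is nonrigid (defaults to `t1`'s grid).
#' @export
compose <- function(t1, t2, grid = NULL) {
  if (inherits(t1, "affine_transform") && inherits(t2, "affine_transform"))
    return(affine_transform(t2$matrix %*% t1$matrix))
  if (is.null(grid)) {
    if (inherits(t1, "deformation_field"))
      grid <- volume3d(array(0, t1$dim), affine = t1$grid$affine)
    else stop("compose needs a grid when t1 is affine and t2 is nonrigid")
  }
  w <- grid_world_coords(grid)
  y <- transform_points(t2, transform_points(t1, w))
  disp <- array(y - w, c(dim(grid$data), 3))
  deformation_field(disp, grid)
}

## NCC between two equal-length intensity vectors; 0 when either is
## (numerically) constant
ncc_vec <- function(a, b) {
  sa <- sd(a); sb <- sd(b)
  if (!is.finite(sa) || !is.finite(sb) || sa < 1e-12 || sb < 1e-12) return(0)
  mean((a - mean(a)) * (b - mean(b))) / (sa * sb) * length(a) / (length(a) - 1)
}

## intensity-weighted centre of mass in world mm
centre_of_mass <- function(vol) {
  w <- pmax(vol$data - min(vol$data), 0)
  W <- grid_world_coords(vol)
  as.vector(colSums(W * as.vector(w)) / sum(w))
}

## build the 4x4 from 9 params (translation mm, rotation rad, log-scale)
## about fixed/moving centres of mass
affine_from_params <- function(theta, c_fixed, c_moving) {
  tr <- theta[1:3]; rot <- theta[4:6] * 180 / pi; ls <- theta[7:9]
  RS <- rot3(rot) %*% diag(exp(ls))
  A <- diag(4)
  A[1:3, 1:3] <- RS
  A[1:3, 4] <- c_moving + tr - RS %*% c_fixed
  A
}

#' Affine registration by NCC optimization
#'
#' Multi-resolution Nelder-Mead over translation, rotation and log-scale
#' (9 dof), initialized at centre-of-mass alignment; deterministic given the
#' inputs and config.
#'
#' @param moving,fixed [volume3d]s with overlapping world extents.
#' @param config List: `levels` (downsampling factors, coarse to fine),
#'   `maxit` evaluations per level, `dof` (`"rigid"` = 6, `"affine"` = 9),
#'   `mask` optional logical array on the fixed grid restricting the metric.
#' @return A `registration_result`: `transform`, `similarity` (final NCC),
#'   `iterations`, `converged`.
#' @export
register_affine <- function(moving, fixed, config = list()) {
  cfg <- modifyList(list(levels = c(2, 1), maxit = c(400, 300), dof = "affine",
                         mask = NULL, max_metric_voxels = 40000,
                         c_fixed = NULL, c_moving = NULL), config)
  if (length(cfg$maxit) < length(cfg$levels))
    cfg$maxit <- rep_len(cfg$maxit, length(cfg$levels))
  bs <- world_bbox(moving); bt <- world_bbox(fixed)
  if (any(bs["hi", ] < bt["lo", ]) || any(bt["hi", ] < bs["lo", ]))
    stop("moving and fixed volumes have disjoint world extents")
  c_f <- if (is.null(cfg$c_fixed)) centre_of_mass(fixed) else cfg$c_fixed
  c_m <- if (is.null(cfg$c_moving)) centre_of_mass(moving) else cfg$c_moving
  npar <- if (cfg$dof == "rigid") 6L else 9L
  theta <- rep(0, 9)
  total_it <- 0L; conv <- TRUE; sim <- NA_real_
  for (li in seq_along(cfg$levels)) {
    lev <- cfg$levels[li]
    f <- fixed; for (s in seq_len(log2(max(lev, 1)))) f <- downsample2(f)
    fw <- grid_world_coords(f)
    fdat <- as.vector(f$data)
    mask <- if (!is.null(cfg$mask) && lev == 1) as.vector(cfg$mask) else NULL
    if (!is.null(mask)) { fw <- fw[mask, , drop = FALSE]; fdat <- fdat[mask] }
    # deterministic stride subsampling keeps the metric cost bounded
    if (length(fdat) > cfg$max_metric_voxels) {
      keep <- seq(1, length(fdat),
                  by = ceiling(length(fdat) / cfg$max_metric_voxels))
      fw <- fw[keep, , drop = FALSE]; fdat <- fdat[keep]
    }
    mdat <- as.double(moving$data); mdim <- dim(moving$data)
    minv <- solve(moving$affine)
    obj <- function(th) {
      th9 <- theta; th9[seq_len(npar)] <- th
      A <- affine_from_params(th9, c_f, c_m)
      y <- sweep(fw %*% t(A[1:3, 1:3]), 2, A[1:3, 4], `+`)
      v <- sweep(y %*% t(minv[1:3, 1:3]), 2, minv[1:3, 4], `+`)
      w <- interp3_cpp(mdat, mdim, v[, 1], v[, 2], v[, 3], 0L)
      -ncc_vec(w, fdat)
    }
    scale <- c(rep(2, 3), rep(0.05, 3), rep(0.05, 3))[seq_len(npar)]
    fit <- stats::optim(theta[seq_len(npar)], obj, method = "Nelder-Mead",
                        control = list(maxit = cfg$maxit[li], parscale = scale,
                                       reltol = 1e-7))
    theta[seq_len(npar)] <- fit$par
    total_it <- total_it + fit$counts[["function"]]
    sim <- -fit$value
    lconv <- fit$convergence == 0
    # plateau check: restart until no further improvement (at most 3 times);
    # a restart that cannot improve the similarity counts as converged
    tries <- 0L
    while (!lconv && tries < 3L) {
      re <- stats::optim(theta[seq_len(npar)], obj, method = "Nelder-Mead",
                         control = list(maxit = 100, parscale = scale,
                                        reltol = 1e-7))
      if (-re$value > sim) theta[seq_len(npar)] <- re$par
      lconv <- (-re$value - sim) < 1e-5
      sim <- max(sim, -re$value)
      total_it <- total_it + re$counts[["function"]]
      tries <- tries + 1L
    }
    conv <- lconv    # convergence judged at the finest level reached
  }
  res <- list(transform = affine_transform(affine_from_params(theta, c_f, c_m)),
              similarity = sim, iterations = total_it, converged = conv)
  class(res) <- "registration_result"
  res
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> %s, NCC %.4f, %d evaluations%s%s\n",
              class(x$transform)[1], x$similarity, x$iterations,
              if (isTRUE(x$converged)) ", converged" else "",
              if (isTRUE(x$folding)) ", FOLDING WARNING" else ""))
  invisible(x)
}

#' Registration presets
#'
#' Multi-resolution schedules for the free-form deformation. `"coarse"`:
#' one half-resolution level with 8-voxel control spacing. `"fine"`: a
#' half-resolution 8-voxel level followed by full-resolution levels at 4-
#' and 2-voxel control spacing. Spacings are in full-resolution voxels; the
#' schedules are package choices tuned on phantoms, not taken from any
#' external engine.
#' @param name `"coarse"` or `"fine"`.
#' @export
reg_preset <- function(name = c("coarse", "fine")) {
  name <- match.arg(name)
  if (name == "coarse")
    list(levels = list(list(ds = 2, spacing = 8, iters = 40)),
         lambda = 0.02, step0 = 1, smooth_sigma = 1)
  else
    list(levels = list(list(ds = 2, spacing = 8, iters = 40),
                       list(ds = 1, spacing = 4, iters = 60),
                       list(ds = 1, spacing = 2, iters = 120)),
         lambda = 0.02, step0 = 1, smooth_sigma = 0.5)
}

## bending energy of the control lattice and its gradient (sum over axes of
## squared second differences, per displacement component)
bending_energy <- function(coef) {
  cd <- dim(coef)
  e <- 0; g <- array(0, cd)
  for (ax in 1:3) {
    n <- cd[ax]
    if (n < 3) next
    idx <- function(off) {
      ix <- list(seq_len(cd[1]), seq_len(cd[2]), seq_len(cd[3]), seq_len(cd[4]))
      ix[[ax]] <- seq_len(n - 2) + off
      do.call(`[`, c(list(coef), ix, list(drop = FALSE)))
    }
    d2 <- idx(2) - 2 * idx(1) + idx(0)
    e <- e + sum(d2^2)
    gi <- function(off, val, garr) {
      ix <- list(seq_len(cd[1]), seq_len(cd[2]), seq_len(cd[3]), seq_len(cd[4]))
      ix[[ax]] <- seq_len(n - 2) + off
      do.call(`[<-`, c(list(garr), ix, list(do.call(`[`, c(list(garr), ix, list(drop = FALSE))) + val)))
    }
    g <- gi(0, 2 * d2, g); g <- gi(1, -4 * d2, g); g <- gi(2, 2 * d2, g)
  }
  list(value = e, grad = g)
}

blur_volume <- function(vol, sigma) {
  if (sigma <= 0) return(vol)
  volume3d(array(gauss_blur3_cpp(as.double(vol$data), dim(vol$data), sigma),
                 dim(vol$data)), affine = vol$affine)
}

#' Nonrigid (free-form deformation) registration
#'
#' Cubic B-spline control-lattice refinement of an initial affine
#' alignment: steepest ascent on normalized cross-correlation with a
#' bending-energy penalty, backtracking line search (monotone in the
#' penalized objective, step reset each iteration), over a coarse-to-fine
#' pyramid. Images are lightly smoothed at each level so the trilinear
#' interpolation landscape is differentiable in practice. A final
#' Jacobian-determinant check flags folding.
#'
#' @param moving,fixed [volume3d]s.
#' @param config A [reg_preset] list (or compatible): `levels` with `ds`
#'   (downsampling factor), `spacing` (control spacing in full-resolution
#'   voxels), `iters`; `lambda` bending-energy weight; `step0` initial step
#'   (mm, measured at the largest control-point update); `smooth_sigma`
#'   metric smoothing in voxels at full resolution.
#' @param initial An `affine_transform` initialization (default identity).
#' @param verbose Print per-level progress.
#' @return A `registration_result` whose `transform` is a
#'   `deformation_field` (the affine is folded in); `folding` flags
#'   Jacobian sign violations beyond the 1\% guard.
#' @export
register_nonrigid <- function(moving, fixed, config = reg_preset("fine"),
                              initial = NULL, verbose = FALSE) {
  if (is.null(initial)) initial <- affine_transform(diag(4))
  A <- initial$matrix
  # moving resampled once through the affine onto the fixed grid; the field
  # u then acts in fixed-grid world coordinates: phi(x) = A (x + u(x))
  M0 <- apply_transform(moving, initial, fixed, mode = "linear")
  u_dense <- NULL   # accumulated displacement, on the current level grid
  total_it <- 0L; sim <- NA_real_
  ctrl_spacing_used <- NA_real_
  for (lv in config$levels) {
    f <- fixed; m0 <- M0
    for (s in seq_len(log2(max(lv$ds, 1)))) { f <- downsample2(f); m0 <- downsample2(m0) }
    if (lv$ds == 1 && config$smooth_sigma > 0) {
      f <- blur_volume(f, config$smooth_sigma)
      m0 <- blur_volume(m0, config$smooth_sigma)
    }
    d <- dim(f$data); nvox <- prod(d)
    spacing_vox <- max(lv$spacing / lv$ds, 1)
    ctrl_spacing_used <- lv$spacing
    cdim <- floor((d - 1) / spacing_vox) + 4
    coef <- array(0, c(cdim, 3))
    ncoef <- length(coef)
    u_prev <- if (is.null(u_dense)) array(0, c(d, 3)) else {
      arr <- vapply(1:3, function(c) {
        uv <- volume3d(u_dense$disp[, , , c], affine = u_dense$aff)
        as.vector(resample(uv, f, mode = "linear")$data)
      }, numeric(nvox))
      array(arr, c(d, 3))
    }
    fw <- grid_world_coords(f)
    fdat <- as.vector(f$data)
    m0inv <- solve(m0$affine)
    m0dat <- as.double(m0$data); m0dim <- dim(m0$data)
    warp <- function(u) {
      y <- fw + matrix(u, ncol = 3)
      v <- sweep(y %*% t(m0inv[1:3, 1:3]), 2, m0inv[1:3, 4], `+`)
      interp3_cpp(m0dat, m0dim, v[, 1], v[, 2], v[, 3], 0L)
    }
    mf <- mean(fdat); sf <- sd(fdat); n <- length(fdat)
    if (sf < 1e-12) next
    ev <- function(coef) {
      u <- u_prev + array(bspline_eval_cpp(as.double(coef), cdim, d, spacing_vox),
                          c(d, 3))
      w <- warp(u)
      be <- bending_energy(coef)
      list(u = u, w = w, be = be, ncc = ncc_vec(w, fdat),
           obj = ncc_vec(w, fdat) - config$lambda * be$value / ncoef)
    }
    cur <- ev(coef)
    ncc0 <- cur$ncc
    for (it in seq_len(lv$iters)) {
      w <- cur$w; mw <- mean(w); sw <- sd(w); ncc <- cur$ncc
      if (sw < 1e-12) break
      dncc_dw <- ((fdat - mf) / (sw * sf) - ncc * (w - mw) / sw^2) / (n - 1)
      warr <- array(w, d)
      gw <- array(0, c(d, 3))
      gw[2:(d[1] - 1), , , 1] <- (warr[3:d[1], , ] - warr[1:(d[1] - 2), , ]) / (2 * f$spacing[1])
      gw[, 2:(d[2] - 1), , 2] <- (warr[, 3:d[2], ] - warr[, 1:(d[2] - 2), ]) / (2 * f$spacing[2])
      gw[, , 2:(d[3] - 1), 3] <- (warr[, , 3:d[3]] - warr[, , 1:(d[3] - 2)]) / (2 * f$spacing[3])
      dense_grad <- gw * array(rep(dncc_dw, 3), c(d, 3))
      gcoef <- array(bspline_adjoint_cpp(as.double(dense_grad), d, cdim, spacing_vox),
                     c(cdim, 3))
      gcoef <- gcoef - config$lambda * cur$be$grad / ncoef
      nrm <- sqrt(gcoef[, , , 1]^2 + gcoef[, , , 2]^2 + gcoef[, , , 3]^2)
      if (max(nrm) < 1e-14) break
      gdir <- gcoef / max(nrm)      # step = largest control-point move in mm
      step <- config$step0
      accepted <- FALSE
      while (step > 1e-3) {
        cand <- ev(coef + step * gdir)
        if (cand$obj > cur$obj + 1e-12) {
          coef <- coef + step * gdir
          cur <- cand
          accepted <- TRUE
          break
        }
        step <- step / 2
      }
      total_it <- total_it + 1L
      if (!accepted) break
    }
    if (verbose)
      cat(sprintf("  level ds=%d sp=%g: ncc %.6f -> %.6f\n",
                  lv$ds, lv$spacing, ncc0, cur$ncc))
    sim <- cur$ncc
    u_dense <- list(disp = array(cur$u, c(d, 3)), aff = f$affine)
  }
  # final dense field on the full fixed grid
  dfin <- dim(fixed$data)
  arr <- vapply(1:3, function(c) {
    uv <- volume3d(u_dense$disp[, , , c], affine = u_dense$aff)
    as.vector(resample(uv, fixed, mode = "linear")$data)
  }, numeric(prod(dfin)))
  field <- deformation_field(array(arr, c(dfin, 3)), fixed, affine = A,
                             control_spacing = ctrl_spacing_used)
  jac <- jacobian_positive_fraction(field)
  res <- list(transform = field, similarity = sim, iterations = total_it,
              converged = TRUE, folding = jac < 0.99, jacobian_positive = jac)
  class(res) <- "registration_result"
  res
}

## fraction of voxels where the overall map has positive Jacobian
## determinant (finite differences of x + u(x), times sign of det(A))
jacobian_positive_fraction <- function(field) {
  d <- field$dim
  if (any(d < 3)) return(1)
  J <- array(0, c(d - 2, 3, 3))
  sp <- field$grid$spacing
  vx <- field$grid$affine[1:3, 1:3] / rep(sp, each = 3)  # voxel step dirs
  for (c in 1:3) {
    u <- field$disp[, , , c]
    J[, , , c, 1] <- (u[3:d[1], 2:(d[2] - 1), 2:(d[3] - 1)] -
                    u[1:(d[1] - 2), 2:(d[2] - 1), 2:(d[3] - 1)]) / (2 * sp[1])
    J[, , , c, 2] <- (u[2:(d[1] - 1), 3:d[2], 2:(d[3] - 1)] -
                    u[2:(d[1] - 1), 1:(d[2] - 2), 2:(d[3] - 1)]) / (2 * sp[2])
    J[, , , c, 3] <- (u[2:(d[1] - 1), 2:(d[2] - 1), 3:d[3]] -
                    u[2:(d[1] - 1), 2:(d[2] - 1), 1:(d[3] - 2)]) / (2 * sp[3])
  }
  # det(I + du/dx) with du/dx expressed in the world frame; for orthogonal
  # grids the voxel-step frame differs by a rotation, leaving det unchanged
  a11 <- 1 + J[, , , 1, 1]; a12 <- J[, , , 1, 2]; a13 <- J[, , , 1, 3]
  a21 <- J[, , , 2, 1]; a22 <- 1 + J[, , , 2, 2]; a23 <- J[, , , 2, 3]
  a31 <- J[, , , 3, 1]; a32 <- J[, , , 3, 2]; a33 <- 1 + J[, , , 3, 3]
  det <- a11 * (a22 * a33 - a23 * a32) - a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31)
  det <- det * sign(det(field$affine[1:3, 1:3]))
  mean(det > 0)
}

#' Serialize a transform
#'
#' Affines as a 4x4 text matrix; deformation fields as a 4D NIfTI of mm
#' displacements plus the affine text matrix alongside.
#' @param t Transform.
#' @param path Output path (affine: a text file; field: `.nii.gz`, with
#'   `<path>.affine.txt` next to it).
#' @export
write_transform <- function(t, path) {
  if (inherits(t, "affine_transform")) {
    write(t(t$matrix), path, ncolumns = 4)
  } else {
    img <- RNifti::asNifti(t$disp)
    aff <- structure(t$grid$affine, code = 2L)
    RNifti::`sform<-`(img, aff)
    RNifti::writeNifti(img, path)
    write(t(t$affine), paste0(path, ".affine.txt"), ncolumns = 4)
  }
  invisible(path)
}
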