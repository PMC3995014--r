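## Seeded synthetic 3D brain phantoms: a large head ellipsoid (intracranial
## volume proxy), ventricle-like CSF bodies, and two curved hippocampus-like
## structures built as unions of three overlapping ellipsoids (a curved shape
## stresses nonrigid registration more than a single ellipsoid). Atrophy is
## modelled as isotropic radius scaling plus partial signal change toward the
## CSF intensity, mirroring how sclerotic hippocampi present on T1 images.

## run expr with a local RNG state seeded from `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv())
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## one global seed fans out to per-component child seeds by fixed offsets
child_seed <- function(seed, offset) {
  (as.numeric(seed) * 7919 + offset * 104729) %% 2147483629
}

#' Specify a synthetic brain phantom
#'
#' @param shape Grid size (voxels), default 64 x 64 x 48 (desk scale).
#' @param spacing Voxel size in mm, default 2 mm isotropic.
#' @param head_radius Base head semi-axis scale in mm (the head ellipsoid has
#'   semi-axes `head_radius * c(0.92, 1, 0.78) * head_scale`).
#' @param hippo_radii Semi-axes in mm of each of the three overlapping
#'   ellipsoids forming one hippocampus.
#' @param atrophy Named length-2 vector, per-side radius scale in (0.3, 1];
#'   1 = normal.
#' @param signal_change Fraction of the hippocampus-to-CSF intensity gap
#'   applied per unit of atrophy (sclerosis combines volume loss with signal
#'   change).
#' @param jitter_trans,jitter_rot SD of per-side pose jitter (mm,
#'   degrees).
#' @param head_scale Multiplicative head size factor (ICV variability).
#' @param intensities Named levels for background, CSF, brain, hippocampus.
#' @param bias_amp Amplitude of the smooth multiplicative intensity bias.
#' @param noise_sd Additive Gaussian noise SD (intensity units).
#' @param seed Integer; fully determines the phantom.
#' @param pose_seed Seed for geometry jitter; defaults to a child of `seed`
#'   so that changing `seed` alone changes only noise/bias realization when
#'   `pose_seed` is held fixed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 48), spacing = c(2, 2, 2),
                         head_radius = 48,
                         hippo_radii = c(6.3, 7.6, 5.8),
                         atrophy = c(left = 1, right = 1),
                         signal_change = 0.5,
                         jitter_trans = 1.5, jitter_rot = 3,
                         head_scale = 1,
                         intensities = c(background = 0, csf = 40,
                                         brain = 100, hippocampus = 135),
                         bias_amp = 0.1, noise_sd = 4,
                         seed = 1, pose_seed = NULL) {
  stopifnot(length(shape) == 3, all(shape >= 8), all(spacing > 0),
            length(atrophy) == 2, noise_sd >= 0, bias_amp >= 0)
  if (any(atrophy <= 0.3) || any(atrophy > 1))
    stop("atrophy factors must lie in (0.3, 1]")
  if (is.null(pose_seed)) pose_seed <- child_seed(seed, 1)
  structure(list(shape = as.integer(shape), spacing = spacing,
                 head_radius = head_radius, hippo_radii = hippo_radii,
                 atrophy = atrophy, signal_change = signal_change,
                 jitter_trans = jitter_trans, jitter_rot = jitter_rot,
                 head_scale = head_scale, intensities = intensities,
                 bias_amp = bias_amp, noise_sd = noise_sd,
                 seed = seed, pose_seed = pose_seed),
            class = "phantom_spec")
}

rot3 <- function(deg) {
  a <- deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1]); cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

## logical vector over W (n x 3 world mm): inside ellipsoid
inside_ellipsoid <- function(W, center, radii, R = diag(3)) {
  q <- sweep(W, 2, center) %*% R
  rowSums(sweep(q, 2, radii, `/`)^2) <= 1
}

#' Generate a phantom brain with ground-truth hippocampus labels
#'
#' @param spec A [phantom_spec].
#' @return A list of class `phantom` with elements `image` ([volume3d]),
#'   `label` ([label_volume], 1 = left, 2 = right), `icv_mm3` (rasterized
#'   head volume), and `volumes_mm3` (per-side true label volumes).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  grid <- volume3d(array(0, d), spacing = spec$spacing)
  W <- grid_world_coords(grid)
  bb <- world_bbox(grid)
  lev <- spec$intensities

  pose <- with_seed(spec$pose_seed, {
    lapply(1:2, function(s) list(
      trans = rnorm(3, 0, spec$jitter_trans),
      rot = rnorm(3, 0, spec$jitter_rot)))
  })

  head_r <- spec$head_radius * c(0.92, 1, 0.78) * spec$head_scale
  check_fit <- function(center, rmax, what) {
    if (any(center - rmax < bb["lo", ] - 1e-9) ||
        any(center + rmax > bb["hi", ] + 1e-9))
      stop(what, " exceeds the phantom grid")
  }
  check_fit(c(0, 0, 0), head_r, "head ellipsoid")
  head <- inside_ellipsoid(W, c(0, 0, 0), head_r)

  vent <- rep(FALSE, nrow(W))
  for (sx in c(-1, 1)) {
    vc <- c(sx * 9, 6, 6) * spec$head_scale
    vr <- c(5, 15, 8) * spec$head_scale
    vent <- vent | inside_ellipsoid(W, vc, vr)
  }

  lab <- integer(nrow(W))
  vol_side <- c(left = 0, right = 0)
  arc <- rbind(c(1.5, -9, 2.5), c(0, 0, 0), c(1.5, 9, 2.5))  # curved arc
  for (s in 1:2) {                    # 1 = left, 2 = right
    sx <- if (s == 1) -1 else 1
    af <- spec$atrophy[s]
    R <- rot3(pose[[s]]$rot)
    base <- c(sx * 21, -6, -9) * spec$head_scale + pose[[s]]$trans
    radii <- spec$hippo_radii * af
    m <- rep(FALSE, nrow(W))
    for (a in 1:3) {
      off <- arc[a, ] * c(sx, 1, 1) * af
      center <- base + as.vector(R %*% off)
      check_fit(center, max(radii), "hippocampus")
      m <- m | inside_ellipsoid(W, center, radii, R)
    }
    lab[m] <- s
    vol_side[s] <- sum(m) * voxel_volume(grid)
  }

  img <- rep(lev[["background"]], nrow(W))
  img[head] <- lev[["brain"]]
  img[vent & head] <- lev[["csf"]]
  for (s in 1:2) {
    hl <- lev[["hippocampus"]] +
      spec$signal_change * (1 - spec$atrophy[s]) *
        (lev[["csf"]] - lev[["hippocampus"]])
    img[lab == s] <- hl
  }

  img <- with_seed(child_seed(spec$seed, 2), {
    ext <- (bb["hi", ] - bb["lo", ]) / 2
    w1 <- sweep(W, 2, ext, `/`)            # normalized coords in [-1,1]
    cf <- runif(3, -1, 1)
    bias <- 1 + spec$bias_amp * as.vector(w1 %*% cf) / sqrt(3)
    img * bias + rnorm(length(img), 0, spec$noise_sd)
  })

  image <- volume3d(array(img, d), affine = grid$affine)
  label <- label_volume(array(lab, d), grid = grid, labels = c(1L, 2L))
  structure(list(image = image, label = label,
                 icv_mm3 = sum(head) * voxel_volume(grid),
                 volumes_mm3 = vol_side, spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> seed %s, ICV %.1f cm^3, hippocampi L %.2f / R %.2f cm^3\n",
              format(x$spec$seed), x$icv_mm3 / 1000,
              x$volumes_mm3[1] / 1000, x$volumes_mm3[2] / 1000))
  invisible(x)
}

## largest-remainder apportionment of n into round(n * frac) with sum n
largest_remainder <- function(n, frac) {
  raw <- n * frac
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Generate a synthetic template database
#'
#' A stand-in for a clinical template library: `n` phantoms with jittered
#' pose and head size and a requested mix of atrophy classes, with per-entry
#' ground truth recorded in the manifest.
#'
#' @param n Number of templates (>= 2).
#' @param base_spec A [phantom_spec] supplying everything not varied here.
#' @param atrophy_mix Named fractions for classes `left`, `right`,
#'   `bilateral`, `normal`; must sum to 1 (largest-remainder rounding to
#'   counts).
#' @param atrophy_range Range the affected-side scale factor is drawn from.
#' @param normal_range Range for unaffected sides.
#' @param head_scale_sd SD of the per-subject head-size factor.
#' @param seed Database-level seed.
#' @return An object of class `template_db`: `entries` (list of
#'   id/image/label) and `meta` (data frame manifest).
#' @export
make_template_database <- function(n, base_spec = phantom_spec(),
                                   atrophy_mix = c(left = 0.25, right = 0.25,
                                                   bilateral = 0.25, normal = 0.25),
                                   atrophy_range = c(0.55, 0.8),
                                   normal_range = c(0.95, 1),
                                   head_scale_sd = 0.04,
                                   seed = 1) {
  if (n < 2) stop("a template database needs at least 2 entries")
  if (abs(sum(atrophy_mix) - 1) > 1e-8)
    stop("atrophy_mix fractions must sum to 1")
  classes <- c("left", "right", "bilateral", "normal")
  counts <- largest_remainder(n, atrophy_mix[classes])
  cls <- rep(classes, counts)
  entries <- vector("list", n)
  meta <- vector("list", n)
  for (i in seq_len(n)) {
    si <- child_seed(seed, 100 + i)
    draws <- with_seed(si, list(
      af = runif(2, atrophy_range[1], atrophy_range[2]),
      nf = runif(2, normal_range[1], normal_range[2]),
      hs = max(0.85, min(1.15, 1 + rnorm(1, 0, head_scale_sd)))))
    atroph <- switch(cls[i],
      left = c(left = draws$af[1], right = draws$nf[2]),
      right = c(left = draws$nf[1], right = draws$af[2]),
      bilateral = c(left = draws$af[1], right = draws$af[2]),
      normal = c(left = draws$nf[1], right = draws$nf[2]))
    sp <- base_spec
    sp$atrophy <- atroph
    sp$head_scale <- draws$hs
    sp$seed <- child_seed(si, 3)
    sp$pose_seed <- child_seed(si, 4)
    ph <- make_phantom(sp)
    id <- sprintf("tpl%03d", i)
    entries[[i]] <- list(id = id, image = ph$image, label = ph$label)
    meta[[i]] <- data.frame(id = id, class = cls[i],
                            vol_left_mm3 = ph$volumes_mm3[["left"]],
                            vol_right_mm3 = ph$volumes_mm3[["right"]],
                            icv_mm3 = ph$icv_mm3, seed = sp$seed)
  }
  structure(list(entries = entries, meta = do.call(rbind, meta)),
            class = "template_db")
}

#' @export
print.template_db <- function(x, ...) {
  cat(sprintf("<template_db> %d entries\n", length(x$entries)))
  print(table(x$meta$class))
  invisible(x)
}

#' Specify a simulated rater
#'
#' The STAPLE generative model: a rater keeps each true foreground voxel
#' with probability `sensitivity` and marks each background voxel with
#' probability `1 - specificity`, independently.
#'
#' @param sensitivity,specificity Values in (0, 1).
#' @param seed Integer seed.
#' @export
rater_spec <- function(sensitivity, specificity, seed = 1) {
  stopifnot(sensitivity > 0, sensitivity < 1, specificity > 0, specificity < 1)
  structure(list(sensitivity = sensitivity, specificity = specificity,
                 seed = seed), class = "rater_spec")
}

#' Simulate a rater's segmentation of a known truth
#'
#' @param truth Binary [label_volume].
#' @param rater A [rater_spec].
#' @return Binary [label_volume] with independent voxelwise errors.
#' @export
simulate_rater <- function(truth, rater) {
  stopifnot(inherits(truth, "label_volume"), inherits(rater, "rater_spec"))
  fg <- truth$data > 0
  out <- with_seed(rater$seed, {
    o <- integer(length(fg))
    o[fg] <- rbinom(sum(fg), 1, rater$sensitivity)
    o[!fg] <- rbinom(sum(!fg), 1, 1 - rater$specificity)
    o
  })
  label_volume(array(out, dim(truth$data)), grid = truth, labels = 1L)
}
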