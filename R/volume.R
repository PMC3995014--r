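#' @useDynLib stepseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rbinom sd cor coef lm quantile
#' @importFrom utils write.csv read.csv head modifyList
NULL

GRID_TOL <- 1e-5

#' Construct a 3D scalar volume
#'
#' The anatomical unit everything in the pipeline operates on: a 3D array of
#' intensities together with its voxel spacing (mm) and a 4x4 affine mapping
#' 0-based voxel indices to world coordinates in mm.
#'
#' @param data 3D numeric array.
#' @param spacing Numeric length-3, voxel size in mm; must be positive.
#'   Ignored when `affine` is given (derived from it instead).
#' @param affine 4x4 voxel-index-to-world matrix. Defaults to a diagonal
#'   affine with the grid centred on the world origin.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  if (length(dim(data)) != 3L) stop("data must be a 3D array")
  if (is.null(affine)) {
    stopifnot(length(spacing) == 3L, all(spacing > 0))
    affine <- diag(c(spacing, 1))
    affine[1:3, 4] <- -(dim(data) - 1) / 2 * spacing
  }
  affine <- unclass(affine)[1:4, 1:4]
  if (abs(det(affine)) < 1e-12) stop("affine is singular")
  if (any(!is.finite(data))) stop("volume data contains non-finite values")
  spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(spacing <= 0)) stop("voxel spacing must be strictly positive")
  structure(list(data = data, spacing = spacing, affine = affine),
            class = "volume3d")
}

#' Construct a label volume
#'
#' A small-integer mask on the same grid as an anatomical [volume3d]. Binary
#' masks use {0,1}; two-sided hippocampal labels use {0 = background,
#' 1 = left, 2 = right}.
#'
#' @param data 3D array of integers drawn from `labels` plus 0.
#' @param grid A `volume3d` (or `label_volume`) supplying spacing/affine, or
#'   `NULL` for a centred default grid with `spacing`.
#' @param labels Permitted non-zero label values.
#' @inheritParams volume3d
#' @return An object of class `label_volume` (inherits `volume3d`).
#' @export
label_volume <- function(data, grid = NULL, spacing = c(1, 1, 1), labels = NULL) {
  vals <- unique(as.vector(data))
  if (is.null(labels)) labels <- sort(setdiff(vals, 0))
  if (!all(vals %in% c(0, labels)))
    stop("label values outside the declared label set {0, ",
         paste(labels, collapse = ","), "}")
  storage.mode(data) <- "integer"
  v <- if (is.null(grid)) volume3d(data, spacing = spacing)
       else volume3d(data, affine = grid$affine)
  v$labels <- as.integer(labels)
  class(v) <- c("label_volume", "volume3d")
  v
}

#' @export
print.volume3d <- function(x, ...) {
  kind <- if (inherits(x, "label_volume")) "label_volume" else "volume3d"
  cat(sprintf("<%s> %s voxels, spacing %s mm\n", kind,
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = " x ")))
  if (inherits(x, "label_volume"))
    cat("  labels:", paste(x$labels, collapse = ", "),
        " foreground voxels:", sum(x$data > 0), "\n")
  else
    cat(sprintf("  intensity range [%.4g, %.4g]\n",
                min(x$data), max(x$data)))
  invisible(x)
}

#' Do two volumes share a grid?
#'
#' Shape must match exactly; affine entries within `tol` (float32 headers).
#' @param a,b Volumes.
#' @param tol Absolute tolerance on affine entries.
#' @export
same_grid <- function(a, b, tol = GRID_TOL) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$affine - b$affine)) <= tol
}

## 0-based voxel index matrix (n x 3) -> world mm (n x 3)
voxel_to_world <- function(affine, ijk) {
  ijk <- matrix(ijk, ncol = 3)
  sweep(ijk %*% t(affine[1:3, 1:3]), 2, affine[1:3, 4], `+`)
}

world_to_voxel <- function(affine, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  inv <- solve(affine)
  sweep(xyz %*% t(inv[1:3, 1:3]), 2, inv[1:3, 4], `+`)
}

## world coordinates of every voxel centre, as an n x 3 matrix (fastest
## index first, matching R array linearisation); memoized per grid since
## registration recomputes this constantly
.grid_cache <- new.env(parent = emptyenv())
grid_world_coords <- function(vol) {
  d <- dim(vol$data)
  key <- paste(c(d, signif(vol$affine, 10)), collapse = "|")
  hit <- .grid_cache[[key]]
  if (!is.null(hit)) return(hit)
  ijk <- cbind(rep.int(seq_len(d[1]) - 1, d[2] * d[3]),
               rep.int(rep(seq_len(d[2]) - 1, each = d[1]), d[3]),
               rep(seq_len(d[3]) - 1, each = d[1] * d[2]))
  w <- voxel_to_world(vol$affine, ijk)
  if (length(ls(.grid_cache)) > 64) rm(list = ls(.grid_cache), envir = .grid_cache)
  .grid_cache[[key]] <- w
  w
}

## world-space bounding box (voxel centres) of a grid
world_bbox <- function(vol) {
  d <- dim(vol$data) - 1
  corners <- as.matrix(expand.grid(c(0, d[1]), c(0, d[2]), c(0, d[3])))
  w <- voxel_to_world(vol$affine, corners)
  rbind(lo = apply(w, 2, min), hi = apply(w, 2, max))
}

#' Read a NIfTI volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param label If `TRUE`, return a [label_volume] (values validated against
#'   the integers present).
#' @return A [volume3d] or [label_volume] with spacing/affine from the header.
#' @export
read_volume <- function(path, label = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) != 3L) stop("not a 3D volume: ", path, " (dim field has ",
                             length(dm), " dimensions)")
  aff <- unclass(RNifti::xform(img))[1:4, 1:4]
  if (abs(det(aff)) < 1e-12) stop("corrupt header in ", path,
                                  ": affine (srow/qform) has zero determinant")
  dat <- as.array(img)
  attributes(dat) <- list(dim = dm)
  if (any(!is.finite(dat))) stop("volume contains NaN/Inf intensities: ", path)
  if (label) {
    if (max(abs(dat - round(dat))) > 1e-6)
      stop("label file has non-integer values: ", path)
    label_volume(round(dat), grid = volume3d(dat, affine = aff))
  } else volume3d(dat, affine = aff)
}

#' Write a volume to NIfTI
#'
#' Labels are written with an integer on-disk datatype, intensities as
#' float64.
#' @param vol A [volume3d] or [label_volume].
#' @param path Output path (`.nii` / `.nii.gz`); parent must exist.
#' @export
write_volume <- function(vol, path) {
  if (!dir.exists(dirname(path)))
    stop("cannot write ", path, ": directory does not exist")
  dtype <- if (inherits(vol, "label_volume")) "int16" else "double"
  img <- RNifti::asNifti(vol$data)
  aff <- structure(vol$affine, code = 2L)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::sform(img) <- aff
  RNifti::qform(img) <- aff
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' Resample a volume onto another grid
#'
#' Intensities are interpolated trilinearly, labels with nearest-neighbour
#' by default; regions outside the source field of view are filled with 0.
#'
#' @param vol Source [volume3d] or [label_volume].
#' @param target_grid A volume (or grid-bearing object) defining the output
#'   grid.
#' @param mode `"linear"` or `"nearest"`; default `"nearest"` for labels,
#'   `"linear"` otherwise.
#' @return Volume of the same kind on the target grid.
#' @export
resample <- function(vol, target_grid, mode = NULL) {
  if (is.null(mode)) mode <- if (inherits(vol, "label_volume")) "nearest" else "linear"
  mode <- match.arg(mode, c("linear", "nearest"))
  bs <- world_bbox(vol); bt <- world_bbox(target_grid)
  if (any(bs["hi", ] < bt["lo", ]) || any(bt["hi", ] < bs["lo", ]))
    stop("source and target grids have disjoint world extents")
  if (same_grid(vol, target_grid) && mode != "linear") return(relabel_like(vol, vol$data, target_grid))
  w <- grid_world_coords(target_grid)
  v <- world_to_voxel(vol$affine, w)
  out <- interp3_cpp(as.double(vol$data), dim(vol$data),
                     v[, 1], v[, 2], v[, 3], as.integer(mode == "nearest"))
  dim(out) <- dim(target_grid$data)
  relabel_like(vol, out, target_grid)
}

## wrap resampled data in the same class as the source
relabel_like <- function(src, data, grid) {
  if (inherits(src, "label_volume")) {
    label_volume(round(data), grid = grid, labels = src$labels)
  } else volume3d(data, affine = grid$affine)
}

## volume of one voxel in mm^3
voxel_volume <- function(vol) abs(det(vol$affine[1:3, 1:3]))

## crop to 1-based index ranges (list of lo, hi length-3), keeping the
## affine consistent
crop_volume <- function(vol, lo, hi) {
  d <- dim(vol$data)
  stopifnot(all(lo >= 1), all(hi <= d), all(lo <= hi))
  dat <- vol$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  aff <- vol$affine
  aff[1:3, 4] <- aff[1:3, 4] + aff[1:3, 1:3] %*% (lo - 1)
  if (inherits(vol, "label_volume"))
    label_volume(dat, grid = volume3d(dat, affine = aff), labels = vol$labels)
  else volume3d(dat, affine = aff)
}

## Gaussian-smooth + factor-2 decimation used by the multi-resolution
## registration pyramid
downsample2 <- function(vol) {
  sm <- gauss_blur3_cpp(as.double(vol$data), dim(vol$data), 1.0)
  d <- dim(vol$data)
  ii <- seq(1, d[1], by = 2); jj <- seq(1, d[2], by = 2); kk <- seq(1, d[3], by = 2)
  dat <- array(sm, d)[ii, jj, kk, drop = FALSE]
  aff <- vol$affine
  aff[1:3, 1:3] <- aff[1:3, 1:3] * 2
  volume3d(dat, affine = aff)
}

#' Binary mask for one side of a two-sided label volume
#'
#' @param label [label_volume] with labels 1 = left, 2 = right.
#' @param side `"left"`, `"right"`, or `"any"` (both sides).
#' @return Binary [label_volume].
#' @export
side_mask <- function(label, side = c("left", "right", "any")) {
  side <- match.arg(side)
  val <- switch(side, left = 1L, right = 2L, any = NULL)
  m <- if (is.null(val)) (label$data > 0) else (label$data == val)
  label_volume(array(as.integer(m), dim(label$data)), grid = label, labels = 1L)
}
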