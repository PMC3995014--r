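## Per-slice closed-polygon contours, emulating how manual hippocampal
## outlines are drawn slice by slice and later converted to voxel masks.
## Polygons live in continuous 0-based voxel coordinates of the in-plane
## axes; vertices of traced masks sit on voxel corners (half-integers).

## trace the boundary of one binary slice into closed rectilinear polygons
trace_slice <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  fg <- which(m, arr.ind = TRUE)
  if (nrow(fg) == 0) return(list())
  pad <- matrix(FALSE, nx + 2, ny + 2)
  pad[2:(nx + 1), 2:(ny + 1)] <- m
  # directed boundary edges (interior kept on the left), endpoints encoded
  # as corner lattice keys: corner (i-0.5, j-0.5) in 0-based voxel coords
  # has key (i, j) with i in 0..nx, j in 0..ny
  segs <- list()
  i <- fg[, 1]; j <- fg[, 2]
  at <- function(di, dj) pad[cbind(i + 1 + di, j + 1 + dj)]
  add <- function(keep, from_i, from_j, to_i, to_j) {
    if (any(keep))
      segs[[length(segs) + 1]] <<- cbind(from_i[keep], from_j[keep],
                                         to_i[keep], to_j[keep])
  }
  add(!at(0, -1), i - 1, j - 1, i, j - 1)   # bottom, left-to-right
  add(!at(1, 0), i, j - 1, i, j)            # right, upward
  add(!at(0, 1), i, j, i - 1, j)            # top, right-to-left
  add(!at(-1, 0), i - 1, j, i - 1, j - 1)   # left, downward
  segs <- do.call(rbind, segs)
  key <- function(a, b) a * (ny + 2) + b
  from <- key(segs[, 1], segs[, 2])
  used <- rep(FALSE, nrow(segs))
  by_from <- split(seq_len(nrow(segs)), from)
  polys <- list()
  for (s0 in seq_len(nrow(segs))) {
    if (used[s0]) next
    path <- integer(0)
    s <- s0
    repeat {
      used[s] <- TRUE
      path <- c(path, s)
      nxt_key <- as.character(key(segs[s, 3], segs[s, 4]))
      cand <- by_from[[nxt_key]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0) break
      s <- cand[1]
    }
    verts <- rbind(segs[path, 1:2, drop = FALSE],
                   segs[path[length(path)], 3:4, drop = FALSE])
    # corner key -> voxel coordinate: corner (i, j) sits at (i - 0.5, j - 0.5)
    polys[[length(polys) + 1]] <- cbind(verts[, 1] - 0.5, verts[, 2] - 0.5)
  }
  polys
}

#' Trace per-slice contours from a binary mask
#'
#' Produces closed polygons following the voxel-edge boundary of each
#' slice's foreground, emulating slice-wise manual outlining. In alternate
#' mode only odd-numbered slices are retained (even-indexed slices are
#' dropped), emulating protocols that outline every other slice.
#'
#' @param label Binary [label_volume].
#' @param alternate Keep only alternate (odd 1-based) slices.
#' @param axis Slice axis (default 3).
#' @return An object of class `contour_set`.
#' @export
make_contours <- function(label, alternate = FALSE, axis = 3L) {
  stopifnot(inherits(label, "label_volume"), axis == 3L)
  d <- dim(label$data)
  keep <- seq_len(d[3])
  if (alternate) keep <- keep[keep %% 2 == 1]
  slices <- list()
  for (k in keep) {
    polys <- trace_slice(label$data[, , k] > 0)
    if (length(polys)) slices[[as.character(k)]] <- polys
  }
  structure(list(slices = slices, axis = axis, dim = d,
                 affine = label$affine, spacing = label$spacing,
                 alternate = alternate),
            class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  cat(sprintf("<contour_set> %d slices with contours (%s mode), grid %s\n",
              length(x$slices), if (x$alternate) "alternate-slice" else "all-slice",
              paste(x$dim, collapse = "x")))
  invisible(x)
}

## supersampled polygon rasterization of one slice: a voxel is included iff
## the polygons enclose at least half of its in-plane footprint, judged on a
## sub x sub point grid (boundary-inclusive: >= half the sample points)
rasterize_slice <- function(polys, nx, ny, sub = 4L) {
  vx <- unlist(lapply(polys, function(p) p[, 1]))
  vy <- unlist(lapply(polys, function(p) p[, 2]))
  lens <- vapply(polys, nrow, 0L)
  lo <- c(max(0, floor(min(vx))), max(0, floor(min(vy))))
  hi <- c(min(nx - 1, ceiling(max(vx))), min(ny - 1, ceiling(max(vy))))
  if (any(hi < lo)) return(matrix(FALSE, nx, ny))
  cx <- lo[1]:hi[1]; cy <- lo[2]:hi[2]
  off <- (seq_len(sub) - (sub + 1) / 2) / sub
  ex <- as.vector(outer(cx, off, `+`)); ey <- as.vector(outer(cy, off, `+`))
  pts <- expand.grid(x = ex, y = ey)
  inside <- pip_cpp(pts$x, pts$y, vx, vy, lens)
  counts <- array(inside, c(length(cx), sub, length(cy), sub))
  counts <- apply(counts, c(1, 3), sum)
  m <- matrix(FALSE, nx, ny)
  m[cbind(rep(cx + 1, length(cy)), rep(cy + 1, each = length(cx)))] <-
    as.vector(counts >= sub * sub / 2)
  m
}

#' Convert contours to a voxel mask
#'
#' A voxel is included iff the slice's polygons enclose at least half of its
#' in-plane footprint (boundary inclusive), judged by 16x supersampled
#' point-in-polygon tests. For alternate-slice contour sets each segmented
#' slice is additionally copied onto its unsegmented neighbour, giving the
#' double slice thickness used when only alternate slices are outlined.
#'
#' @param contours A [contour_set].
#' @param sub Supersampling factor per in-plane axis (default 4, i.e. 16
#'   points per voxel).
#' @return Binary [label_volume] on the contour set's grid.
#' @export
contours_to_mask <- function(contours, sub = 4L) {
  stopifnot(inherits(contours, "contour_set"))
  d <- contours$dim
  out <- array(0L, d)
  for (k in names(contours$slices)) {
    polys <- contours$slices[[k]]
    for (p in polys)
      if (nrow(p) < 3) stop("open or degenerate polygon on slice ", k)
    out[, , as.integer(k)] <-
      rasterize_slice(polys, d[1], d[2], sub = sub)
  }
  if (contours$alternate) {
    for (k in as.integer(names(contours$slices))) {
      kk <- k + 1L
      if (kk <= d[3]) out[, , kk] <- out[, , k]
    }
  }
  grid <- volume3d(array(0, d), affine = contours$affine)
  label_volume(out, grid = grid, labels = 1L)
}

#' Write contours as JSON (world-mm vertices)
#'
#' @param contours A [contour_set].
#' @param path Output path.
#' @export
write_contours <- function(contours, path) {
  aff <- contours$affine
  slices <- lapply(names(contours$slices), function(k) {
    polys <- lapply(contours$slices[[k]], function(p) {
      ijk <- cbind(p[, 1], p[, 2], as.integer(k) - 1)
      unname(voxel_to_world(aff, ijk))
    })
    list(slice = as.integer(k), polygons = polys)
  })
  obj <- list(axis = contours$axis, dim = contours$dim,
              affine = unname(contours$affine),
              alternate = contours$alternate, slices = slices)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read contours from JSON
#' @param path Path written by [write_contours].
#' @return A [contour_set].
#' @export
read_contours <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  aff <- matrix(unlist(obj$affine), 4, 4, byrow = TRUE)
  # jsonlite returns matrices row-major faithful; ensure 4x4 orientation
  if (!isTRUE(all.equal(dim(as.matrix(obj$affine)), c(4L, 4L))))
    stop("malformed contour file: affine")
  aff <- as.matrix(obj$affine)
  slices <- list()
  n <- if (is.data.frame(obj$slices)) nrow(obj$slices) else length(obj$slices)
  for (i in seq_len(n)) {
    entry <- if (is.data.frame(obj$slices)) obj$slices[i, ] else obj$slices[[i]]
    k <- as.integer(entry$slice)
    polys <- entry$polygons
    if (is.data.frame(polys) || is.matrix(polys)) polys <- list(polys)
    if (length(polys) == 1 && is.list(polys[[1]]) && !is.matrix(polys[[1]]) &&
        !is.data.frame(polys[[1]])) polys <- polys[[1]]
    slices[[as.character(k)]] <- lapply(polys, function(pw) {
      pw <- as.matrix(pw)
      v <- world_to_voxel(aff, pw)
      cbind(v[, 1], v[, 2])
    })
  }
  structure(list(slices = slices, axis = obj$axis,
                 dim = as.integer(obj$dim), affine = aff,
                 spacing = sqrt(colSums(aff[1:3, 1:3]^2)),
                 alternate = isTRUE(obj$alternate)),
            class = "contour_set")
}
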