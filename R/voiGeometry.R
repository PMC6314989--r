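# twice the signed area of a polygon given as an n x 2 matrix
polygonArea2 <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1L)
  sum(p[, 1L] * p[j, 2L] - p[j, 1L] * p[, 2L])
}

# convex and simple: all nonzero cross products share one sign
isConvexQuad <- function(p) {
  n <- nrow(p)
  cr <- numeric(n)
  for (v in seq_len(n)) {
    a <- p[v, ]
    b <- p[v %% n + 1L, ]
    cc <- p[(v + 1L) %% n + 1L, ]
    e1 <- b - a; e2 <- cc - b
    cr[v] <- e1[1L] * e2[2L] - e1[2L] * e2[1L]
  }
  all(cr >= -1e-12) || all(cr <= 1e-12)
}

#' Construct a trapezoid search VOI
#'
#' @param corners 4x2 matrix (or length-8 vector, row-wise) of (i, j) voxel
#'   coordinates on the centre slice; must form a simple convex
#'   quadrilateral. Either winding order is accepted.
#' @param sliceRange inclusive `c(kMin, kMax)`.
#' @return a [TrapezoidVoi-class].
#' @export
#' @examples
#' trapezoidVoi(rbind(c(2, 2), c(10, 2), c(10, 6), c(2, 6)), c(4, 4))
trapezoidVoi <- function(corners, sliceRange) {
  if (!is.matrix(corners)) corners <- matrix(corners, ncol = 2, byrow = TRUE)
  if (polygonArea2(corners) < 0)       # normalise to counter-clockwise
    corners <- corners[4:1, , drop = FALSE]
  new("TrapezoidVoi", corners = corners,
      sliceRange = as.integer(sliceRange))
}

#' Rasterize a trapezoid VOI onto a reference grid
#'
#' Voxel membership is centre inclusion: a voxel belongs to the VOI when its
#' in-plane centre lies inside or on the boundary of the quadrilateral. The
#' in-plane footprint is replicated identically on every slice of
#' `sliceRange` (a prism).
#'
#' @param voi a [TrapezoidVoi-class].
#' @param reference a [VolumeImage-class] providing the grid.
#' @return a [MaskVolume-class].
#' @export
rasterizeTrapezoid <- function(voi, reference) {
  stopifnot(is(voi, "TrapezoidVoi"), is(reference, "VolumeImage"))
  validObject(voi)
  d <- dim(reference@data)
  p <- voi@corners
  if (any(p[, 1L] < 1 - 1e-9) || any(p[, 1L] > d[1L] + 1e-9) ||
      any(p[, 2L] < 1 - 1e-9) || any(p[, 2L] > d[2L] + 1e-9))
    stop("geometry error: trapezoid corners outside the grid", call. = FALSE)
  if (voi@sliceRange[2L] > d[3L])
    stop("geometry error: sliceRange outside the grid", call. = FALSE)
  # half-plane test against all four CCW edges, boundary inclusive
  gi <- rep(seq_len(d[1L]), times = d[2L])
  gj <- rep(seq_len(d[2L]), each = d[1L])
  inside <- rep(TRUE, d[1L] * d[2L])
  for (v in 1:4) {
    a <- p[v, ]; b <- p[v %% 4L + 1L, ]
    cr <- (b[1L] - a[1L]) * (gj - a[2L]) - (b[2L] - a[2L]) * (gi - a[1L])
    inside <- inside & (cr >= -1e-9)
  }
  plane <- matrix(inside, d[1L], d[2L])
  m <- array(FALSE, d)
  for (k in voi@sliceRange[1L]:voi@sliceRange[2L]) m[, , k] <- plane
  MaskVolume(m, reference@spacing)
}

#' Split a mask into right and left hemisphere halves
#'
#' The midline is a plane orthogonal to the hemisphere axis. With
#' `midline = "auto"` it passes through the centroid of the mask along that
#' axis. Voxels whose coordinate is exactly on the midline go to the right
#' half (fixed tie rule, for determinism across runs and operators).
#'
#' @param mask a [MaskVolume-class] (nonempty).
#' @param axis hemisphere axis (1, 2 or 3; default 1).
#' @param midline `"auto"` or a voxel coordinate.
#' @param rightIsLow if `TRUE` (default) the right hemisphere is at lower
#'   indices along `axis`; orientation is configuration, not inferred.
#' @return list with `MaskVolume` elements `right` and `left`; their union
#'   is `mask` and their intersection empty.
#' @export
splitHalves <- function(mask, axis = 1L, midline = "auto", rightIsLow = TRUE) {
  stopifnot(is(mask, "MaskVolume"), axis %in% 1:3)
  if (!any(mask@data)) stop("value error: cannot split an empty mask", call. = FALSE)
  idx <- which(mask@data, arr.ind = TRUE)
  if (identical(midline, "auto")) midline <- mean(idx[, axis])
  coord <- slice.index(mask@data, axis)
  # the exact-midline tie always goes to the right half
  right <- if (rightIsLow) mask@data & (coord <= midline)
           else mask@data & (coord >= midline)
  left <- mask@data & !right
  list(right = MaskVolume(right, mask@spacing),
       left = MaskVolume(left, mask@spacing))
}

#' Build a background (reference-region) mask
#'
#' Accepts either an explicit [MaskVolume-class] (returned unchanged after
#' an alignment check) or a box specification
#' `list(corner = c(i, j, k), extent = c(di, dj, dk))` in voxels, covering
#' `corner` to `corner + extent - 1` inclusive.
#'
#' @param spec mask or box list.
#' @param reference a [VolumeImage-class].
#' @return a [MaskVolume-class] with at least one voxel.
#' @export
backgroundMask <- function(spec, reference) {
  stopifnot(is(reference, "VolumeImage"))
  if (is(spec, "MaskVolume")) {
    checkAligned(spec, reference, what = "background mask")
    if (!any(spec@data))
      stop("geometry error: background mask is empty", call. = FALSE)
    return(spec)
  }
  if (!is.list(spec) || is.null(spec$corner) || is.null(spec$extent))
    stop("background spec must be a MaskVolume or list(corner, extent)", call. = FALSE)
  corner <- as.integer(unlist(spec$corner)); extent <- as.integer(unlist(spec$extent))
  d <- dim(reference@data)
  if (any(extent < 1L)) stop("geometry error: box extent must be >= 1", call. = FALSE)
  hi <- corner + extent - 1L
  if (any(corner < 1L) || any(hi > d))
    stop(sprintf("geometry error: background box [%s]..[%s] exceeds grid (%s)",
                 paste(corner, collapse = ","), paste(hi, collapse = ","),
                 paste(d, collapse = "x")), call. = FALSE)
  m <- array(FALSE, d)
  m[corner[1L]:hi[1L], corner[2L]:hi[2L], corner[3L]:hi[3L]] <- TRUE
  MaskVolume(m, reference@spacing)
}

#' Centroid of a mask in voxel coordinates
#'
#' @param mask a nonempty [MaskVolume-class].
#' @return numeric(3) mean (i, j, k) of the true voxels.
#' @export
maskCentroid <- function(mask) {
  stopifnot(is(mask, "MaskVolume"))
  if (!any(mask@data)) stop("value error: empty mask", call. = FALSE)
  colMeans(which(mask@data, arr.ind = TRUE))
}
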