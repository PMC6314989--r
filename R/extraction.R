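#' Construct extraction parameters
#'
#' @param standardVolumeMl standard striatal volume in mL; the reported
#'   average striatal volume 11.2 mL is the default.
#' @param connectivity 6, 18 or 26 (default 26, the most permissive standard
#'   3D neighbourhood, least likely to fragment low-uptake cases).
#' @param allowOverlap allow the left mask to reuse right-mask voxels.
#' @param mode `"greedy"` or `"top_n_unconstrained"`.
#' @return an [ExtractionParams-class].
#' @export
extractionParams <- function(standardVolumeMl = 11.2, connectivity = 26L,
                             allowOverlap = FALSE, mode = "greedy") {
  new("ExtractionParams", standardVolumeMl = as.numeric(standardVolumeMl),
      connectivity = as.integer(connectivity), allowOverlap = allowOverlap,
      mode = mode)
}

#' Voxel budget for a physical volume
#'
#' Converts a volume in mL into a whole number of voxels on a given grid:
#' `round(volumeMl * 1000 / voxelVolumeMm3)` with ties rounded away from
#' zero. For the 11.2 mL standard striatal volume on a 2.2 mm isotropic
#' grid this gives 1052 voxels per side.
#'
#' @param volumeMl volume in mL (> 0).
#' @param spacing numeric(3) voxel size in mm (> 0).
#' @return integer voxel count.
#' @export
#' @examples
#' voxelCountForVolume(11.2, c(2.2, 2.2, 2.2))  # 1052
voxelCountForVolume <- function(volumeMl, spacing) {
  if (!isTRUE(volumeMl > 0)) stop("value error: volumeMl must be > 0", call. = FALSE)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("value error: spacing must be 3 positive values", call. = FALSE)
  x <- volumeMl * 1000 / prod(spacing)
  as.integer(floor(x + 0.5))   # ties away from zero (x is positive)
}

#' Neighbourhood offsets for a 3D connectivity order
#'
#' @param connectivity 6 (faces), 18 (faces + edges) or 26 (full cube).
#' @return integer matrix, one `(di, dj, dk)` offset per row.
#' @export
connectivityOffsets <- function(connectivity = 26L) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("value error: connectivity must be 6, 18 or 26", call. = FALSE)
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  ord <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord >= 1 & ord <= 2, "26" = ord >= 1)
  storage.mode(g) <- "integer"
  unname(g[keep, , drop = FALSE])
}

linearIndex <- function(ijk, d) {
  (ijk[, 3L] - 1L) * (d[1L] * d[2L]) + (ijk[, 2L] - 1L) * d[1L] + ijk[, 1L]
}

#' Find the peak voxel inside a search region
#'
#' Returns the index of the maximum image value within the search mask.
#' Ties are broken lexicographically by (k, j, i), smallest first, so the
#' result is deterministic.
#'
#' @param image a [VolumeImage-class].
#' @param search a [MaskVolume-class] aligned to `image`.
#' @return integer(3) voxel index `(i, j, k)`.
#' @export
findPeak <- function(image, search) {
  stopifnot(is(image, "VolumeImage"), is(search, "MaskVolume"))
  checkAligned(search, image, what = "search mask")
  lin <- which(search@data)
  if (!length(lin)) stop("value error: empty search mask", call. = FALSE)
  v <- image@data[lin]
  best <- lin[v == max(v)]
  # column-major linear order (i fastest) == lexicographic (k, j, i)
  as.integer(arrayInd(min(best), dim(image@data)))
}

#' Grow a connected fixed-size high-intensity region
#'
#' Greedy best-first growth: the region starts at the seed; at each step the
#' highest-valued voxel of the search region that neighbours the current
#' region (under the chosen connectivity) is added, ties broken by
#' lexicographic (k, j, i) order, until exactly `nVoxels` voxels are
#' included. The result is connected by construction and growth is nested:
#' growing to `n` then to `n + m` voxels from the same seed yields a
#' superset.
#'
#' @param image a [VolumeImage-class].
#' @param seed integer(3) voxel index, must lie inside `search`.
#' @param search a [MaskVolume-class] aligned to `image`.
#' @param nVoxels target region size (>= 1).
#' @param connectivity 6, 18 or 26.
#' @return a [MaskVolume-class] with exactly `nVoxels` voxels.
#' @section Shortfall: if fewer than `nVoxels` voxels are reachable from the
#'   seed within `search`, an error reports the reachable count — a smaller
#'   mask would silently change the SBR denominator semantics, so there is
#'   no truncation.
#' @export
growFixedVolume <- function(image, seed, search, nVoxels, connectivity = 26L) {
  stopifnot(is(image, "VolumeImage"), is(search, "MaskVolume"))
  checkAligned(search, image, what = "search mask")
  d <- dim(image@data)
  seed <- as.integer(seed)
  if (length(seed) != 3L || any(seed < 1L) || any(seed > d))
    stop("value error: seed outside the grid", call. = FALSE)
  if (!search@data[seed[1L], seed[2L], seed[3L]])
    stop("value error: seed outside the search region", call. = FALSE)
  if (!isTRUE(nVoxels >= 1)) stop("value error: nVoxels must be >= 1", call. = FALSE)
  seedLin <- linearIndex(matrix(seed, 1L), d) - 1L
  lin <- growGreedyC(as.vector(image@data), as.integer(d),
                     as.vector(search@data), as.integer(seedLin),
                     as.integer(nVoxels), connectivityOffsets(connectivity))
  if (length(lin) < nVoxels)
    stop(sprintf("shortfall error: only %d voxels reachable from the seed, %d requested",
                 length(lin), nVoxels), call. = FALSE)
  m <- array(FALSE, d)
  m[lin] <- TRUE
  MaskVolume(m, image@spacing)
}

# global top-n voxels inside the search region (no adjacency constraint);
# the non-default comparison mode
topNUnconstrained <- function(image, search, nVoxels) {
  lin <- which(search@data)
  if (length(lin) < nVoxels)
    stop(sprintf("shortfall error: only %d voxels in the search region, %d requested",
                 length(lin), nVoxels), call. = FALSE)
  v <- image@data[lin]
  ord <- order(-v, lin)   # ties by (k, j, i) via linear index
  m <- array(FALSE, dim(image@data))
  m[lin[ord[seq_len(nVoxels)]]] <- TRUE
  MaskVolume(m, image@spacing)
}

#' Extract bilateral striatal VOIs of standard volume
#'
#' The full fixed-volume extraction: the voxel budget `n` is derived from
#' the standard striatal volume and the grid spacing; the search VOI is
#' split into hemisphere halves; the right peak voxel is found in the right
#' half and a connected cluster of exactly `n` high-intensity voxels is
#' grown from it within that half; the left side follows, with any
#' right-mask voxels removed from its search region unless `allowOverlap`
#' is set. Confining growth to the half keeps a low-uptake side's mask on
#' its own striatum instead of creeping toward the brighter contralateral
#' side.
#'
#' @param image a [VolumeImage-class].
#' @param voiT search region: a [MaskVolume-class] or a
#'   [TrapezoidVoi-class] (rasterized onto `image`).
#' @param params an [ExtractionParams-class].
#' @param axis hemisphere axis (default 1).
#' @param rightIsLow orientation of the right hemisphere along `axis`.
#' @return a [StriatalMasks-class].
#' @export
extractBilateral <- function(image, voiT, params = extractionParams(),
                             axis = 1L, rightIsLow = TRUE) {
  stopifnot(is(image, "VolumeImage"), is(params, "ExtractionParams"))
  validObject(params)
  if (is(voiT, "TrapezoidVoi")) voiT <- rasterizeTrapezoid(voiT, image)
  checkAligned(voiT, image, what = "VOI_t")
  if (!any(voiT@data)) stop("value error: empty VOI_t", call. = FALSE)
  n <- voxelCountForVolume(params@standardVolumeMl, image@spacing)
  halves <- splitHalves(voiT, axis = axis, rightIsLow = rightIsLow)

  growSide <- function(half, searchRegion, side) {
    tryCatch({
      peak <- findPeak(image, half)
      mask <- if (params@mode == "greedy")
        growFixedVolume(image, peak, searchRegion, n, params@connectivity)
      else topNUnconstrained(image, half, n)
      list(peak = peak, mask = mask)
    }, error = function(e) stop(sprintf("%s side: %s", side, conditionMessage(e)),
                                call. = FALSE))
  }

  r <- growSide(halves$right, halves$right, "right")
  leftSearch <- if (params@allowOverlap) halves$left else
    MaskVolume(halves$left@data & !r$mask@data, voiT@spacing)
  l <- growSide(leftSearch, leftSearch, "left")

  new("StriatalMasks", right = r$mask, left = l$mask,
      nVoxelsRequested = as.integer(n),
      peaks = list(right = r$peak, left = l$peak))
}
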