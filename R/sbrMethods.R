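sbrResult <- function(method, side, total, bgMean, voxVolMl, sbr, extras = list()) {
  new("SbrResult", method = method, side = side, totalVoiCount = total,
      bgMeanPerVoxel = bgMean, bgConcPerMl = bgMean / voxVolMl, sbr = sbr,
      extras = extras)
}

checkBg <- function(image, voiBg, voiSt = NULL) {
  checkAligned(voiBg, image, what = "VOI_bg")
  if (!any(voiBg@data)) stop("value error: empty background VOI", call. = FALSE)
  if (!is.null(voiSt) && any(voiBg@data & voiSt@data))
    stop("validation error: background VOI overlaps the striatal VOI", call. = FALSE)
  bgMean <- mean(image@data[voiBg@data])
  if (!isTRUE(bgMean > 0))
    stop("value error: background mean count must be > 0", call. = FALSE)
  bgMean
}

#' Count-based specific binding ratio
#'
#' SBR from a fixed-volume striatal VOI against a background reference:
#' the striatal count concentration is the total VOI count divided by the
#' standard striatal volume (11.2 mL by default, not the realized mask
#' volume); the background concentration is the VOI_bg mean count per voxel
#' divided by the voxel volume in mL. Then
#' `sbr = (Cst - Cbg) / Cbg`.
#'
#' All concentrations are per mL; because the mask holds
#' `voxelCountForVolume(standardVolumeMl, spacing)` voxels this equals the
#' per-voxel mean ratio up to the sub-voxel rounding of the budget (about
#' 0.02% on a 2.2 mm grid).
#'
#' @param image a [VolumeImage-class].
#' @param voiSt striatal [MaskVolume-class].
#' @param voiBg background [MaskVolume-class], disjoint from `voiSt`.
#' @param standardVolumeMl denominator volume in mL (default 11.2).
#' @param side label recorded in the result.
#' @return an [SbrResult-class].
#' @export
sbrCountBased <- function(image, voiSt, voiBg, standardVolumeMl = 11.2,
                          side = "right") {
  stopifnot(is(image, "VolumeImage"))
  checkAligned(voiSt, image, what = "VOI_st")
  if (!any(voiSt@data)) stop("value error: empty striatal VOI", call. = FALSE)
  bgMean <- checkBg(image, voiBg, voiSt)
  voxMl <- prod(image@spacing) / 1000
  total <- sum(image@data[voiSt@data])
  cSt <- total / standardVolumeMl
  cBg <- bgMean / voxMl
  sbrResult("count_based", side, total, bgMean, voxMl, (cSt - cBg) / cBg,
            extras = list(Vs = standardVolumeMl, nVoxels = sum(voiSt@data)))
}

#' Tossici-Bolt specific binding ratio
#'
#' Large fixed-geometry VOI estimator: with `Qvoi` the total count inside
#' the large VOI, `Cr` the reference (background) concentration per mL,
#' `Vvoi` the VOI volume and `Vs` the standard striatal volume,
#' `sbr = (Qvoi / Cr - Vvoi) / Vs`. The extras record
#' `R = Vvoi / Vs`, the amplification constant of the method.
#'
#' @param image a [VolumeImage-class].
#' @param voiLarge large VOI enclosing the striatum ([MaskVolume-class]).
#' @param voiBg background [MaskVolume-class].
#' @param standardVolumeMl `Vs` in mL (default 11.2).
#' @param side label recorded in the result.
#' @return an [SbrResult-class].
#' @export
sbrTossiciBolt <- function(image, voiLarge, voiBg, standardVolumeMl = 11.2,
                           side = "right") {
  stopifnot(is(image, "VolumeImage"))
  checkAligned(voiLarge, image, what = "large VOI")
  if (!any(voiLarge@data)) stop("value error: empty large VOI", call. = FALSE)
  bgMean <- checkBg(image, voiBg)
  voxMl <- prod(image@spacing) / 1000
  q <- sum(image@data[voiLarge@data])
  cR <- bgMean / voxMl
  vVoi <- sum(voiLarge@data) * voxMl
  sbr <- (q / cR - vVoi) / standardVolumeMl
  sbrResult("tossici_bolt", side, q, bgMean, voxMl, sbr,
            extras = list(Vvoi = vVoi, Vs = standardVolumeMl,
                          R = vVoi / standardVolumeMl, Cr = cR))
}

#' Tossici-Bolt algebraic identity
#'
#' Computes the Tossici-Bolt SBR by its two printed algebraic forms,
#' `(Qvoi/Cr - Vvoi)/Vs` and `R * (Cvoi/Cr - 1)` with
#' `Cvoi = Qvoi/Vvoi` and `R = Vvoi/Vs`; the two must agree to relative
#' tolerance 1e-10.
#'
#' @inheritParams sbrTossiciBolt
#' @return named numeric(2): `form1`, `form2`.
#' @export
tbIdentity <- function(image, voiLarge, voiBg, standardVolumeMl = 11.2) {
  res <- sbrTossiciBolt(image, voiLarge, voiBg, standardVolumeMl)
  q <- res@totalVoiCount
  cR <- res@extras$Cr
  vVoi <- res@extras$Vvoi
  cVoi <- q / vVoi
  form2 <- (vVoi / standardVolumeMl) * (cVoi / cR - 1)
  c(form1 = res@sbr, form2 = form2)
}

#' Build a Tossici-Bolt large VOI (elliptical cylinder)
#'
#' A fixed-geometry VOI centred on a striatum: an elliptical cylinder along
#' the slice axis with 44 mm axial thickness (the method's fixed value) and
#' configurable in-plane radii. Voxel membership is centre inclusion; a
#' slice belongs to the cylinder when its centre lies within
#' `thicknessMm / 2` of the centre slice.
#'
#' @param centre integer(3) voxel index of the cylinder centre.
#' @param reference a [VolumeImage-class].
#' @param radiiMm in-plane (i, j) radii in mm; the default (26, 36) encloses
#'   the phantom striatum with margin for PSF spill-out.
#' @param thicknessMm axial thickness in mm (default 44).
#' @return a [MaskVolume-class].
#' @export
buildTbVoi <- function(centre, reference, radiiMm = c(26, 36), thicknessMm = 44) {
  stopifnot(is(reference, "VolumeImage"))
  d <- dim(reference@data)
  centre <- as.numeric(centre)
  if (length(centre) != 3L || any(centre < 1) || any(centre > d))
    stop("geometry error: cylinder centre outside the grid", call. = FALSE)
  sp <- reference@spacing
  di <- (seq_len(d[1L]) - centre[1L]) * sp[1L] / radiiMm[1L]
  dj <- (seq_len(d[2L]) - centre[2L]) * sp[2L] / radiiMm[2L]
  dk <- abs(seq_len(d[3L]) - centre[3L]) * sp[3L]
  disc <- outer(di^2, dj^2, "+") <= 1
  m <- array(FALSE, d)
  for (k in which(dk <= thicknessMm / 2)) m[, , k] <- disc
  if (!any(m)) stop("geometry error: cylinder does not cover any voxel", call. = FALSE)
  ext <- (d - 1) * sp
  if ((centre[1L] - 1) * sp[1L] < radiiMm[1L] ||
      (d[1L] - centre[1L]) * sp[1L] < radiiMm[1L] ||
      (centre[2L] - 1) * sp[2L] < radiiMm[2L] ||
      (d[2L] - centre[2L]) * sp[2L] < radiiMm[2L])
    stop("geometry error: cylinder exceeds the grid in-plane", call. = FALSE)
  MaskVolume(m, sp)
}

#' Bilateral SBR summary for both methods
#'
#' Convenience wrapper: per-side count-based SBR from extracted striatal
#' masks, per-side Tossici-Bolt SBR from large VOIs, plus the bilateral
#' mean (arithmetic mean of the side SBRs) and the dominant-side value
#' (the lower of the two, i.e. the more affected side).
#'
#' @param image a [VolumeImage-class].
#' @param masks a [StriatalMasks-class].
#' @param voiBg background [MaskVolume-class].
#' @param tbRight,tbLeft large VOIs per side (omit to skip Tossici-Bolt).
#' @param standardVolumeMl `Vs` in mL.
#' @return nested list: `$count_based` and (if requested) `$tossici_bolt`,
#'   each with `right`, `left` ([SbrResult-class]) and numeric
#'   `bilateral_mean` and `dominant`.
#' @export
sbrBilateral <- function(image, masks, voiBg, tbRight = NULL, tbLeft = NULL,
                         standardVolumeMl = 11.2) {
  stopifnot(is(masks, "StriatalMasks"))
  out <- list()
  r <- sbrCountBased(image, masks@right, voiBg, standardVolumeMl, side = "right")
  l <- sbrCountBased(image, masks@left, voiBg, standardVolumeMl, side = "left")
  out$count_based <- list(right = r, left = l,
                          bilateral_mean = (r@sbr + l@sbr) / 2,
                          dominant = min(r@sbr, l@sbr))
  if (!is.null(tbRight) && !is.null(tbLeft)) {
    tr <- sbrTossiciBolt(image, tbRight, voiBg, standardVolumeMl, side = "right")
    tl <- sbrTossiciBolt(image, tbLeft, voiBg, standardVolumeMl, side = "left")
    out$tossici_bolt <- list(right = tr, left = tl,
                             bilateral_mean = (tr@sbr + tl@sbr) / 2,
                             dominant = min(tr@sbr, tl@sbr))
  }
  out
}
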