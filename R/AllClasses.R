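#' VolumeImage: a 3D scalar count grid with voxel spacing
#'
#' Container for a reconstructed SPECT volume (or any 3D scalar grid).
#' Voxel indices are 1-based `(i, j, k)`; by convention axis `i` is the
#' left-right (hemisphere) axis, but all consumers take the axis as an
#' argument because scanner orientation cannot be assumed.
#'
#' @slot data numeric 3D array of counts (arbitrary scale).
#' @slot spacing numeric(3), per-axis voxel edge length in mm (all > 0).
#' @slot meta free-form provenance list.
#' @export
setClass("VolumeImage",
  representation(data = "array", spacing = "numeric", meta = "list"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "data must be a 3D array")
    if (length(object@spacing) != 3L || !all(is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 positive finite values (mm)")
    bad <- which(!is.finite(object@data))
    if (length(bad)) {
      idx <- arrayInd(bad[1L], dim(object@data))
      msg <- c(msg, sprintf("data contains non-finite voxel, first at (%d, %d, %d)",
                            idx[1L], idx[2L], idx[3L]))
    }
    if (length(msg)) msg else TRUE
  })

#' MaskVolume: a boolean VOI grid aligned to a VolumeImage
#'
#' @slot data logical 3D array; `TRUE` marks voxels inside the VOI.
#' @slot spacing numeric(3), per-axis mm, must match the image the mask is
#'   applied to (checked by every consuming operation).
#' @export
setClass("MaskVolume",
  representation(data = "array", spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L || !is.logical(object@data))
      msg <- c(msg, "data must be a logical 3D array")
    if (anyNA(object@data))
      msg <- c(msg, "mask contains NA voxels")
    if (length(object@spacing) != 3L || !all(is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 positive finite values (mm)")
    if (length(msg)) msg else TRUE
  })

#' TrapezoidVoi: in-plane quadrilateral replicated over a slice range
#'
#' The striatal search region VOI_t: four in-plane corner points on the
#' centre slice, extruded as a prism over an inclusive slice range. The
#' corners must form a simple convex quadrilateral (either winding order is
#' accepted and normalised to counter-clockwise).
#'
#' @slot corners numeric 4x2 matrix of (i, j) voxel coordinates (1-based,
#'   fractional allowed).
#' @slot sliceRange integer(2), inclusive `[kMin, kMax]`.
#' @export
setClass("TrapezoidVoi",
  representation(corners = "matrix", sliceRange = "integer"),
  validity = function(object) {
    msg <- character()
    if (!is.numeric(object@corners) || !all(dim(object@corners) == c(4L, 2L)))
      msg <- c(msg, "corners must be a 4x2 numeric matrix")
    else {
      a <- polygonArea2(object@corners)
      if (abs(a) < 1e-9)
        msg <- c(msg, "degenerate quadrilateral: corners are collinear (zero area)")
      else if (!isConvexQuad(object@corners))
        msg <- c(msg, "corners must form a simple convex quadrilateral")
    }
    if (length(object@sliceRange) != 2L || anyNA(object@sliceRange) ||
        object@sliceRange[1L] > object@sliceRange[2L] || object@sliceRange[1L] < 1L)
      msg <- c(msg, "sliceRange must be inclusive [kMin, kMax] with 1 <= kMin <= kMax")
    if (length(msg)) msg else TRUE
  })

#' ExtractionParams: settings for fixed-volume striatal extraction
#'
#' @slot standardVolumeMl standard striatal volume in mL (default 11.2).
#' @slot connectivity 3D neighbourhood order: 6, 18 or 26 (default 26).
#' @slot sideOrder fixed processing order, `"right-then-left"`.
#' @slot allowOverlap if `FALSE` (default), voxels claimed by the right mask
#'   are removed from the left side's search region.
#' @slot mode `"greedy"` (connected best-first growth, the default) or
#'   `"top_n_unconstrained"` (global top-n voxels per half, for comparison).
#' @export
setClass("ExtractionParams",
  representation(standardVolumeMl = "numeric", connectivity = "integer",
                 sideOrder = "character", allowOverlap = "logical",
                 mode = "character"),
  prototype(standardVolumeMl = 11.2, connectivity = 26L,
            sideOrder = "right-then-left", allowOverlap = FALSE,
            mode = "greedy"),
  validity = function(object) {
    msg <- character()
    if (!isTRUE(object@standardVolumeMl > 0))
      msg <- c(msg, "standardVolumeMl must be > 0")
    if (!object@connectivity %in% c(6L, 18L, 26L))
      msg <- c(msg, "connectivity must be 6, 18 or 26")
    if (!object@mode %in% c("greedy", "top_n_unconstrained"))
      msg <- c(msg, "mode must be 'greedy' or 'top_n_unconstrained'")
    if (!identical(object@sideOrder, "right-then-left"))
      msg <- c(msg, "sideOrder must be 'right-then-left'")
    if (length(msg)) msg else TRUE
  })

#' StriatalMasks: the bilateral extracted striatal VOIs
#'
#' @slot right,left `MaskVolume` per hemisphere, each a single connected
#'   component of exactly `nVoxelsRequested` voxels.
#' @slot nVoxelsRequested the voxel budget derived from the standard volume.
#' @slot peaks list with elements `right` and `left`, each an integer(3)
#'   seed voxel index.
#' @export
setClass("StriatalMasks",
  representation(right = "MaskVolume", left = "MaskVolume",
                 nVoxelsRequested = "integer", peaks = "list"))

#' SbrResult: one specific binding ratio with provenance
#'
#' @slot method `"count_based"` or `"tossici_bolt"`.
#' @slot side `"right"`, `"left"` or `"bilateral_mean"`.
#' @slot totalVoiCount summed counts inside the striatal VOI.
#' @slot bgMeanPerVoxel mean background count per voxel.
#' @slot bgConcPerMl background count concentration per mL.
#' @slot sbr the dimensionless specific binding ratio.
#' @slot extras method-specific values (e.g. `Vvoi`, `Vs`, `R` for the
#'   Tossici-Bolt method).
#' @export
setClass("SbrResult",
  representation(method = "character", side = "character",
                 totalVoiCount = "numeric", bgMeanPerVoxel = "numeric",
                 bgConcPerMl = "numeric", sbr = "numeric", extras = "list"),
  validity = function(object) {
    msg <- character()
    if (!object@method %in% c("count_based", "tossici_bolt"))
      msg <- c(msg, "method must be 'count_based' or 'tossici_bolt'")
    if (!object@side %in% c("right", "left", "bilateral_mean"))
      msg <- c(msg, "side must be 'right', 'left' or 'bilateral_mean'")
    if (!isTRUE(object@bgMeanPerVoxel > 0))
      msg <- c(msg, "bgMeanPerVoxel must be > 0")
    if (length(msg)) msg else TRUE
  })

#' PhantomSpec: generative description of a synthetic DaT-SPECT volume
#'
#' Each striatum is an ellipsoid of uniform activity
#' `backgroundLevel * (1 + trueSbr)` over a uniform nonspecific background,
#' followed by an isotropic Gaussian PSF and optional Poisson noise.
#'
#' @slot shape integer(3) grid dimensions.
#' @slot spacing numeric(3) voxel size in mm.
#' @slot centresMm 2x3 matrix of striatal centres in mm (rows right, left;
#'   mm coordinate of voxel (1,1,1)'s centre is 0).
#' @slot semiAxesMm 2x3 matrix of per-side ellipsoid semi-axes in mm.
#' @slot trueSbr named numeric(2), ground-truth SBR per side (right, left).
#' @slot backgroundLevel nonspecific background, counts/voxel (> 0).
#' @slot psfFwhmMm Gaussian PSF full width at half maximum in mm (0 = none).
#' @slot noise `"none"` or `"poisson"`.
#' @slot countScale multiplier applied before the Poisson draw.
#' @slot seed RNG seed for the noise draw.
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", spacing = "numeric",
                 centresMm = "matrix", semiAxesMm = "matrix",
                 trueSbr = "numeric", backgroundLevel = "numeric",
                 psfFwhmMm = "numeric", noise = "character",
                 countScale = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@shape) != 3L || any(object@shape < 8L))
      msg <- c(msg, "shape must be 3 dimensions, each >= 8")
    if (any(object@spacing <= 0)) msg <- c(msg, "spacing must be > 0")
    if (any(object@trueSbr < 0)) msg <- c(msg, "trueSbr must be >= 0")
    if (!isTRUE(object@backgroundLevel > 0))
      msg <- c(msg, "backgroundLevel must be > 0")
    if (object@psfFwhmMm < 0) msg <- c(msg, "psfFwhmMm must be >= 0")
    if (!object@noise %in% c("none", "poisson"))
      msg <- c(msg, "noise must be 'none' or 'poisson'")
    if (!isTRUE(object@countScale > 0))
      msg <- c(msg, "countScale must be > 0")
    # ellipsoids must fit inside the grid
    ext <- (object@shape - 1) * object@spacing
    for (s in 1:2) {
      lo <- object@centresMm[s, ] - object@semiAxesMm[s, ]
      hi <- object@centresMm[s, ] + object@semiAxesMm[s, ]
      if (any(lo < 0) || any(hi > ext))
        msg <- c(msg, sprintf("%s striatal ellipsoid exceeds the grid",
                              c("right", "left")[s]))
    }
    if (length(msg)) msg else TRUE
  })

#' PhantomTruth: a generated phantom with its ground truth
#'
#' @slot volume the simulated `VolumeImage`.
#' @slot rightMask,leftMask pre-blur ellipsoid supports as `MaskVolume`.
#' @slot trueSbr named numeric(2), per-side ground truth.
#' @slot suggestedVoiT a `TrapezoidVoi` covering both striata.
#' @slot suggestedVoiBg background box spec: list(corner, extent) in voxels.
#' @slot spec the generating `PhantomSpec`.
#' @export
setClass("PhantomTruth",
  representation(volume = "VolumeImage", rightMask = "MaskVolume",
                 leftMask = "MaskVolume", trueSbr = "numeric",
                 suggestedVoiT = "TrapezoidVoi", suggestedVoiBg = "list",
                 spec = "PhantomSpec"))

#' RocSummary: empirical ROC curve with AUC and Youden cutoff
#'
#' @slot thresholds candidate decision thresholds.
#' @slot sensitivity,specificity operating points per threshold.
#' @slot auc area under the curve (trapezoid), in [0, 1].
#' @slot cutoff Youden-optimal threshold.
#' @slot accuracy fraction correctly classified at `cutoff`.
#' @slot direction `"lower_is_positive"` (low SBR = abnormal) or
#'   `"higher_is_positive"`.
#' @export
setClass("RocSummary",
  representation(thresholds = "numeric", sensitivity = "numeric",
                 specificity = "numeric", auc = "numeric", cutoff = "numeric",
                 accuracy = "numeric", direction = "character"),
  validity = function(object) {
    if (object@auc < 0 || object@auc > 1) "auc must lie in [0, 1]" else TRUE
  })
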