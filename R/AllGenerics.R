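#' @export
setGeneric("volumeData", function(x) standardGeneric("volumeData"))
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @export
setGeneric("voxelVolumeMl", function(x) standardGeneric("voxelVolumeMl"))
#' @export
setGeneric("voxelCount", function(x) standardGeneric("voxelCount"))
#' @export
setGeneric("maskVolumeMl", function(x) standardGeneric("maskVolumeMl"))
#' @export
setGeneric("sbrValue", function(x) standardGeneric("sbrValue"))

#' Accessors for volumes, masks and results
#'
#' `volumeData()` returns the raw 3D array, `voxelSpacing()` the per-axis
#' voxel size in mm, `voxelVolumeMl()` the volume of one voxel in mL,
#' `voxelCount()` the number of `TRUE` voxels of a mask, `maskVolumeMl()`
#' the mask volume in mL, and `sbrValue()` the scalar SBR of an
#' [SbrResult-class].
#'
#' @param x a `VolumeImage`, `MaskVolume` or `SbrResult`.
#' @return See the individual descriptions.
#' @name accessors
#' @aliases volumeData voxelSpacing voxelVolumeMl voxelCount maskVolumeMl
#'   sbrValue
NULL

#' @rdname accessors
#' @export
setMethod("volumeData", "VolumeImage", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("volumeData", "MaskVolume", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "VolumeImage", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "MaskVolume", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("voxelVolumeMl", "VolumeImage", function(x) prod(x@spacing) / 1000)
#' @rdname accessors
#' @export
setMethod("voxelVolumeMl", "MaskVolume", function(x) prod(x@spacing) / 1000)
#' @rdname accessors
#' @export
setMethod("voxelCount", "MaskVolume", function(x) sum(x@data))
#' @rdname accessors
#' @export
setMethod("maskVolumeMl", "MaskVolume", function(x) sum(x@data) * prod(x@spacing) / 1000)
#' @rdname accessors
#' @export
setMethod("sbrValue", "SbrResult", function(x) x@sbr)

setMethod("show", "VolumeImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("VolumeImage %dx%dx%d, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  cat(sprintf("  counts: min %.4g, max %.4g, total %.6g\n",
              min(object@data), max(object@data), sum(object@data)))
  if (length(object@meta)) cat("  meta:", paste(names(object@meta), collapse = ", "), "\n")
})

setMethod("show", "MaskVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("MaskVolume %dx%dx%d, %d voxels (%.3f mL)\n",
              d[1], d[2], d[3], sum(object@data),
              sum(object@data) * prod(object@spacing) / 1000))
})

setMethod("show", "SbrResult", function(object) {
  cat(sprintf("SbrResult [%s, %s]: SBR = %.4f\n", object@method, object@side,
              object@sbr))
  cat(sprintf("  total VOI count %.6g, background %.4g counts/voxel (%.4g /mL)\n",
              object@totalVoiCount, object@bgMeanPerVoxel, object@bgConcPerMl))
  if (length(object@extras))
    cat("  extras:", paste(names(object@extras), signif(unlist(object@extras), 5),
                           sep = "=", collapse = ", "), "\n")
})

setMethod("show", "StriatalMasks", function(object) {
  cat(sprintf("StriatalMasks: %d voxels requested per side\n", object@nVoxelsRequested))
  cat(sprintf("  right: %d voxels, peak (%s)\n", sum(object@right@data),
              paste(object@peaks$right, collapse = ", ")))
  cat(sprintf("  left:  %d voxels, peak (%s)\n", sum(object@left@data),
              paste(object@peaks$left, collapse = ", ")))
})

setMethod("show", "PhantomTruth", function(object) {
  d <- dim(object@volume@data)
  cat(sprintf("PhantomTruth %dx%dx%d: true SBR right %.3g, left %.3g\n",
              d[1], d[2], d[3], object@trueSbr[["right"]], object@trueSbr[["left"]]))
})

setMethod("show", "RocSummary", function(object) {
  cat(sprintf("RocSummary: AUC %.4f, cutoff %.4g, accuracy %.1f%% (%s)\n",
              object@auc, object@cutoff, 100 * object@accuracy,
              object@direction))
})
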