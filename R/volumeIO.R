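#' Construct a VolumeImage
#'
#' @param data numeric 3D array of counts.
#' @param spacing numeric(3) voxel size in mm.
#' @param meta optional provenance list.
#' @return a [VolumeImage-class].
#' @export
#' @examples
#' img <- VolumeImage(array(1, c(8, 8, 8)), spacing = c(2.2, 2.2, 2.2))
#' voxelVolumeMl(img)
VolumeImage <- function(data, spacing, meta = list()) {
  storage.mode(data) <- "double"
  new("VolumeImage", data = data, spacing = as.numeric(spacing), meta = meta)
}

#' Construct a MaskVolume
#'
#' @param data logical (or 0/1 numeric) 3D array.
#' @param spacing numeric(3) voxel size in mm.
#' @return a [MaskVolume-class].
#' @export
MaskVolume <- function(data, spacing) {
  d <- dim(data)
  data <- as.logical(data != 0)
  dim(data) <- d
  new("MaskVolume", data = data, spacing = as.numeric(spacing))
}

#' Verify that a mask is aligned to a reference image
#'
#' Every consuming operation refuses misaligned mask/volume pairs; there is
#' no silent resampling.
#'
#' @param mask a [MaskVolume-class].
#' @param reference a [VolumeImage-class] (or another mask).
#' @param what label used in the error message.
#' @return invisibly `TRUE`; errors on mismatch.
#' @export
checkAligned <- function(mask, reference, what = "mask") {
  ds <- dim(mask@data); dr <- dim(reference@data)
  if (!identical(ds, dr))
    stop(sprintf("alignment error: %s shape (%s) does not match reference shape (%s)",
                 what, paste(ds, collapse = "x"), paste(dr, collapse = "x")),
         call. = FALSE)
  if (!isTRUE(all.equal(mask@spacing, reference@spacing, tolerance = 1e-6)))
    stop(sprintf("alignment error: %s spacing (%s) does not match reference spacing (%s)",
                 what, paste(signif(mask@spacing, 6), collapse = ", "),
                 paste(signif(reference@spacing, 6), collapse = ", ")),
         call. = FALSE)
  invisible(TRUE)
}

isNiftiPath <- function(path) grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)

#' Read a 3D volume
#'
#' Reads NIfTI-1 (`.nii` / `.nii.gz`) via RNifti, or the plain-text fallback
#' dialect: a whitespace-separated value file accompanied by a YAML sidecar
#' `<path>.yaml` with keys `shape`, `spacing` and optionally `dtype`
#' (values are stored column-major, first axis fastest).
#'
#' @param path file path.
#' @return a [VolumeImage-class]; spacing is taken from the header/sidecar.
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop(sprintf("format error: no such file '%s'", path),
                               call. = FALSE)
  if (isNiftiPath(path)) {
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e) stop(sprintf("format error reading '%s': %s",
                                                     path, conditionMessage(e)),
                                             call. = FALSE))
    arr <- as.array(img)
    attributes(arr) <- list(dim = dim(arr))
    if (length(dim(arr)) == 4L && dim(arr)[4L] == 1L) {
      arr <- arr[, , , 1L, drop = TRUE]
      dim(arr) <- dim(arr)
    }
    if (length(dim(arr)) != 3L)
      stop(sprintf("format error: '%s' is not a 3D volume", path), call. = FALSE)
    # pixdim is float32 in the header; snap to its 7-digit precision so
    # that write/read round trips preserve typical mm spacings exactly
    sp <- signif(RNifti::pixdim(img)[1:3], 7)
  } else {
    side <- paste0(path, ".yaml")
    if (!file.exists(side))
      stop(sprintf("format error: sidecar '%s' not found", side), call. = FALSE)
    hdr <- yaml::read_yaml(side)
    if (is.null(hdr$shape) || is.null(hdr$spacing))
      stop("format error: sidecar must provide 'shape' and 'spacing'", call. = FALSE)
    vals <- scan(path, what = double(), quiet = TRUE)
    if (length(vals) != prod(unlist(hdr$shape)))
      stop(sprintf("format error: '%s' holds %d values, sidecar shape needs %d",
                   path, length(vals), prod(unlist(hdr$shape))), call. = FALSE)
    arr <- array(vals, unlist(hdr$shape))
    sp <- as.numeric(unlist(hdr$spacing))
  }
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop(sprintf("validation error: '%s' has non-positive voxel spacing (%s)",
                 path, paste(signif(sp, 6), collapse = ", ")), call. = FALSE)
  bad <- which(!is.finite(arr))
  if (length(bad)) {
    idx <- arrayInd(bad[1L], dim(arr))
    stop(sprintf("validation error: non-finite voxel in '%s', first at (%d, %d, %d)",
                 path, idx[1L], idx[2L], idx[3L]), call. = FALSE)
  }
  VolumeImage(arr, sp, meta = list(source = path))
}

#' Write a volume to NIfTI-1 or the text dialect
#'
#' NIfTI output stores doubles so that a write/read round trip is
#' bit-identical; the header spacing equals `voxelSpacing(img)`.
#'
#' @param img a [VolumeImage-class].
#' @param path destination; `.nii`/`.nii.gz` selects NIfTI, anything else
#'   the text + YAML-sidecar dialect.
#' @return invisibly `path`.
#' @export
writeVolume <- function(img, path) {
  stopifnot(is(img, "VolumeImage"))
  if (!dir.exists(dirname(path)))
    stop(sprintf("I/O error: directory '%s' does not exist", dirname(path)),
         call. = FALSE)
  if (isNiftiPath(path)) {
    nii <- RNifti::asNifti(img@data)
    RNifti::pixdim(nii) <- img@spacing
    RNifti::writeNifti(nii, path, datatype = "double")
  } else {
    writeLines(format(as.vector(img@data), digits = 17), path)
    yaml::write_yaml(list(shape = dim(img@data), spacing = img@spacing,
                          dtype = "double"), paste0(path, ".yaml"))
  }
  invisible(path)
}

#' Read a mask, verifying alignment against a reference volume
#'
#' Masks are stored as ordinary 0/1 volumes; any nonzero voxel becomes
#' `TRUE`.
#'
#' @param path file path (NIfTI or text dialect, as [readVolume()]).
#' @param reference the [VolumeImage-class] the mask will be applied to.
#' @return a [MaskVolume-class].
#' @export
readMask <- function(path, reference) {
  stopifnot(is(reference, "VolumeImage"))
  vol <- readVolume(path)
  m <- MaskVolume(vol@data, vol@spacing)
  checkAligned(m, reference, what = sprintf("mask '%s'", path))
  m
}

#' Write a mask as a 0/1 volume
#'
#' @param mask a [MaskVolume-class].
#' @param path destination path.
#' @return invisibly `path`.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "MaskVolume"))
  arr <- array(as.double(mask@data), dim(mask@data))
  writeVolume(VolumeImage(arr, mask@spacing), path)
}
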