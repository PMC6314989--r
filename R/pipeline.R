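# allowed configuration schema: key -> allowed sub-keys (NULL = scalar)
configSchema <- function() {
  list(
    output_dir = NULL, seed = NULL, log_level = NULL,
    phantom = c("shape", "spacing", "true_sbr", "background_level",
                "psf_fwhm_mm", "noise", "count_scale", "right_scale"),
    paths = c("image", "voi_t", "voi_bg"),
    extraction = c("standard_volume_ml", "connectivity", "allow_overlap",
                   "mode", "axis", "right_is_low"),
    tb = c("radii_mm", "thickness_mm"),
    background = c("corner", "extent"),
    voi_t = c("corners", "slice_range")
  )
}

#' Validate a run configuration
#'
#' Checks the configuration list (or YAML file) against the pipeline
#' schema before any computation; unknown keys are rejected.
#'
#' @param config list or path to a YAML file.
#' @return the validated config list.
#' @export
validateConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop(sprintf("schema error: config file '%s' not found", config), call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  schema <- configSchema()
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown))
    stop(sprintf("schema error: unknown config keys: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  for (key in names(config)) {
    allowed <- schema[[key]]
    if (!is.null(allowed) && is.list(config[[key]])) {
      bad <- setdiff(names(config[[key]]), allowed)
      if (length(bad))
        stop(sprintf("schema error: unknown keys under '%s': %s", key,
                     paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  if (is.null(config$phantom) && (is.null(config$paths) || is.null(config$paths$image)))
    stop("schema error: either 'phantom' or 'paths.image' must be provided",
         call. = FALSE)
  if (!is.null(config$paths$image) && !file.exists(config$paths$image))
    stop(sprintf("schema error: image path '%s' does not exist", config$paths$image),
         call. = FALSE)
  config
}

pipelineLog <- function(level, cfgLevel, ...) {
  ranks <- c(debug = 1, info = 2, warn = 3, error = 4)
  if (ranks[[level]] >= ranks[[cfgLevel %||% "info"]])
    message(sprintf("[%s] %s", toupper(level), paste0(...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full SBR pipeline
#'
#' Stages: phantom generation (when a `phantom` block is configured) or
#' image/mask loading, bilateral fixed-volume striatal extraction, SBR by
#' both methods, and a JSON report. Every report embeds the config hash
#' and seed, so identical configurations produce byte-identical reports.
#'
#' @param config list or YAML path; see [validateConfig()].
#' @return invisibly the report list (also written to
#'   `<output_dir>/report.json`, with masks and the phantom volume as
#'   NIfTI files when an output directory is configured).
#' @export
runPipeline <- function(config) {
  config <- validateConfig(config)
  logLv <- config$log_level %||% "info"
  seed <- as.integer(config$seed %||% 1L)
  outDir <- config$output_dir

  if (!is.null(config$phantom)) {
    ph <- config$phantom
    spec <- phantomSpec(
      shape = ph$shape %||% c(128L, 128L, 64L),
      spacing = ph$spacing %||% rep(2.2, 3),
      trueSbr = unlist(ph$true_sbr %||% 3),
      backgroundLevel = ph$background_level %||% 30,
      psfFwhmMm = ph$psf_fwhm_mm %||% 10,
      noise = ph$noise %||% "poisson",
      countScale = ph$count_scale %||% 1,
      seed = seed)
    if (!is.null(ph$right_scale))
      spec@trueSbr["right"] <- spec@trueSbr[["right"]] * ph$right_scale
    pipelineLog("info", logLv, "generating phantom (seed ", seed, ")")
    truth <- generatePhantom(spec)
    image <- truth@volume
    voiT <- rasterizeTrapezoid(truth@suggestedVoiT, image)
    voiBg <- backgroundMask(truth@suggestedVoiBg, image)
  } else {
    pipelineLog("info", logLv, "reading image ", config$paths$image)
    image <- readVolume(config$paths$image)
    truth <- NULL
    voiT <- if (!is.null(config$voi_t))
      rasterizeTrapezoid(trapezoidVoi(matrix(unlist(config$voi_t$corners),
                                             ncol = 2, byrow = TRUE),
                                      unlist(config$voi_t$slice_range)), image)
    else readMask(config$paths$voi_t, image)
    voiBg <- if (!is.null(config$background))
      backgroundMask(list(corner = unlist(config$background$corner),
                          extent = unlist(config$background$extent)), image)
    else readMask(config$paths$voi_bg, image)
  }

  ex <- config$extraction
  params <- extractionParams(
    standardVolumeMl = ex$standard_volume_ml %||% 11.2,
    connectivity = ex$connectivity %||% 26L,
    allowOverlap = isTRUE(ex$allow_overlap),
    mode = ex$mode %||% "greedy")
  axis <- ex$axis %||% 1L
  rightIsLow <- ex$right_is_low %||% TRUE

  masks <- tryCatch(extractBilateral(image, voiT, params, axis = axis,
                                     rightIsLow = rightIsLow),
                    error = function(e) stop(sprintf("stage 'extract': %s",
                                                     conditionMessage(e)),
                                             call. = FALSE))
  tbCfg <- config$tb
  radii <- unlist(tbCfg$radii_mm %||% c(26, 36))
  thick <- tbCfg$thickness_mm %||% 44
  tbVois <- tryCatch(list(
    right = buildTbVoi(maskCentroid(masks@right), image, radii, thick),
    left = buildTbVoi(maskCentroid(masks@left), image, radii, thick)),
    error = function(e) stop(sprintf("stage 'tb_voi': %s", conditionMessage(e)),
                             call. = FALSE))
  res <- tryCatch(
    sbrBilateral(image, masks, voiBg, tbVois$right, tbVois$left,
                 params@standardVolumeMl),
    error = function(e) stop(sprintf("stage 'sbr': %s", conditionMessage(e)),
                             call. = FALSE))

  asRec <- function(x) list(sbr = x@sbr, total_voi_count = x@totalVoiCount,
                            bg_mean_per_voxel = x@bgMeanPerVoxel,
                            bg_conc_per_ml = x@bgConcPerMl, extras = x@extras)
  # the hash covers the scientific configuration, not where output lands
  hashCfg <- config[setdiff(names(config), c("output_dir", "log_level"))]
  report <- list(
    config_hash = rlang::hash(hashCfg), seed = seed,
    n_voxels = masks@nVoxelsRequested,
    peaks = masks@peaks,
    count_based = list(right = asRec(res$count_based$right),
                       left = asRec(res$count_based$left),
                       bilateral_mean = res$count_based$bilateral_mean,
                       dominant = res$count_based$dominant),
    tossici_bolt = list(right = asRec(res$tossici_bolt$right),
                        left = asRec(res$tossici_bolt$left),
                        bilateral_mean = res$tossici_bolt$bilateral_mean,
                        dominant = res$tossici_bolt$dominant))
  if (!is.null(truth)) report$true_sbr <- as.list(truth@trueSbr)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeMask(masks@right, file.path(outDir, "voi_st_right.nii.gz"))
    writeMask(masks@left, file.path(outDir, "voi_st_left.nii.gz"))
    if (!is.null(truth))
      writeVolume(image, file.path(outDir, "phantom.nii.gz"))
    pipelineLog("info", logLv, "report written to ", file.path(outDir, "report.json"))
  }
  invisible(report)
}
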