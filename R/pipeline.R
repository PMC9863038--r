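#' Pipeline configuration
#'
#' One flat configuration object bundling the parameters of every stage.
#' Round-trips unchanged through the YAML config-file format; unknown keys
#' are rejected.
#'
#' @param classifier a [classifierParams()] list.
#' @param detector a [detectorParams()] list.
#' @param inpaint an [inpaintParams()] list.
#' @param enhance list with `gamma` (`NULL` = adaptive) and `denoise`.
#' @param inpaintOriginal inpaint into the original rather than the
#'   enhanced image for low-brightness frames (default `FALSE`: detection
#'   and repair both act on the enhanced frame).
#' @return a nested named list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(classifier = classifierParams(),
                           detector = detectorParams(),
                           inpaint = inpaintParams(),
                           enhance = list(gamma = NULL, denoise = TRUE),
                           inpaintOriginal = FALSE) {
  cfg <- list(classifier = classifier, detector = detector,
              inpaint = inpaint, enhance = enhance,
              inpaintOriginal = isTRUE(inpaintOriginal))
  class(cfg) <- "pipelineConfig"
  cfg
}

#' Read and write pipeline configuration files
#'
#' The file is a flat YAML document of `section.key: value` entries
#' mirroring the parameter names of [pipelineConfig()]. Unknown keys are
#' rejected; missing keys keep their defaults. `NULL`-valued defaults
#' (auto-resolved parameters) are written as YAML nulls.
#'
#' @param path YAML file path.
#' @param config a [pipelineConfig()] object.
#' @return `readPipelineConfig` returns a [pipelineConfig()];
#'   `writePipelineConfig` returns `path` invisibly.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- pipelineConfig()
  for (sec in names(raw)) {
    if (!sec %in% names(cfg))
      stop("unknown config section: ", sec)
    if (sec == "inpaintOriginal") {
      cfg$inpaintOriginal <- isTRUE(raw[[sec]])
      next
    }
    for (key in names(raw[[sec]])) {
      if (!key %in% names(cfg[[sec]]))
        stop("unknown config key: ", sec, ".", key)
      cfg[[sec]][key] <- raw[[sec]][key]   # single bracket keeps NULLs
    }
  }
  cfg
}

#' @rdname readPipelineConfig
#' @export
writePipelineConfig <- function(config, path) {
  raw <- unclass(config)
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' Run the full specular-removal pipeline
#'
#' Executes the four stages in order: brightness classification,
#' enhancement of low-brightness frames, highlight detection, and
#' exemplar-based inpainting of the detected regions (skipped when the
#' mask is empty, in which case the output is byte-identical to the
#' input). The report records the class, the absolute threshold, and per
#' region the search window, fill-step count and the coefficient of
#' variation of the detected area before and after repair.
#'
#' @param image an [RgbImage-class].
#' @param config a [pipelineConfig()] object.
#' @return list with `image` (the repaired frame), `mask` (the detected
#'   [HighlightMask-class]) and `report`.
#' @export
runPipeline <- function(image, config = pipelineConfig()) {
  det <- tryCatch(
    detectHighlights(image, config$detector, config$classifier),
    error = function(e) stop("detection stage failed: ",
                             conditionMessage(e), call. = FALSE))
  target <- if (config$inpaintOriginal) image else det$work
  m <- det$mask@.Data
  report <- list(class = det$class, Th = det$Th,
                 nRegions = 0L, regions = list())
  if (sum(m) == 0L) {
    return(list(image = target, mask = det$mask, report = report))
  }
  regions <- extractRegions(det$mask)
  covBefore <- vapply(regions, function(rg)
    regionCov(target, rg@pixels), numeric(1L))
  inp <- tryCatch(
    inpaintImage(target, det$mask, config$inpaint, report = TRUE),
    error = function(e) stop("inpainting stage failed: ",
                             conditionMessage(e), call. = FALSE))
  covAfter <- vapply(regions, function(rg)
    regionCov(inp$image, rg@pixels), numeric(1L))
  report$nRegions <- length(regions)
  report$regions <- lapply(seq_along(regions), function(i) {
    ri <- if (length(inp$report$regions) >= i) inp$report$regions[[i]]
          else list(window = NULL, steps = NA_integer_, evals = NA_real_)
    list(label = i, nPixels = nrow(regions[[i]]@pixels),
         window = ri$window, steps = ri$steps, evals = ri$evals,
         covBefore = covBefore[i], covAfter = covAfter[i])
  })
  list(image = inp$image, mask = det$mask, report = report)
}
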