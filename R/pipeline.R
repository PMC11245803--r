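## End-to-end orchestration: load -> axes -> clean -> cluster -> trace ->
## calibrate -> aggregate, with a run report of per-stage diagnostics.

#' Build and validate a digitization pipeline configuration
#'
#' @param image_path path to the PNG/JPEG plot image.
#' @param n_curves number of Kaplan-Meier curves in the plot.
#' @param x_start,x_end,x_increment declared time-axis range and tick
#'   increment (required).
#' @param y_start,y_end,y_increment declared probability-axis range and
#'   tick increment (required).
#' @param bg_lightness_threshold background lightness cutoff (default 0.8).
#' @param dark_threshold dark-pixel lightness cutoff (default 0.2).
#' @param ocr_enabled run OCR text removal and label verification
#'   (default FALSE; enabling it requires a tesseract binary).
#' @param knn_k neighbour count for the trace score (default 20).
#' @param hue_boost,light_boost clustering channel weights (defaults 2, 1).
#' @param drop_dark_censor_marks remove near-black pixels (censoring marks
#'   drawn in black) before clustering (default FALSE).
#' @param seed RNG seed for the clustering stage (default 42).
#' @param gap_horizon_frac trace gap-fill horizon as a fraction of the
#'   region extent (default 1: scan to the region edge; see
#'   [tracePath()]).
#' @param output_path optional CSV destination for the curve table.
#' @return A validated configuration (class `kmPipelineConfig`).
#' @export
pipelineConfig <- function(image_path, n_curves,
                           x_start, x_end, x_increment,
                           y_start, y_end, y_increment,
                           bg_lightness_threshold = 0.8,
                           dark_threshold = 0.2,
                           ocr_enabled = FALSE,
                           knn_k = 20,
                           hue_boost = 2,
                           light_boost = 1,
                           drop_dark_censor_marks = FALSE,
                           seed = 42,
                           gap_horizon_frac = 1,
                           output_path = NULL) {
  need <- c("image_path", "n_curves", "x_start", "x_end", "x_increment",
            "y_start", "y_end", "y_increment")
  for (nm in need) {
    v <- get(nm)
    if (missing(image_path) && nm == "image_path") v <- NULL
    if (is.null(v) || length(v) != 1L || (is.numeric(v) && !is.finite(v))) {
      kmStop("kmConfigError", "required configuration field missing: %s", nm)
    }
  }
  if (n_curves < 1 || n_curves != round(n_curves)) {
    kmStop("kmConfigError", "n_curves must be a positive integer")
  }
  if (x_increment <= 0 || y_increment <= 0) {
    kmStop("kmConfigError", "axis increments must be positive")
  }
  if (bg_lightness_threshold <= 0 || bg_lightness_threshold > 1 ||
      dark_threshold <= 0 || dark_threshold >= 1) {
    kmStop("kmConfigError", "lightness thresholds must lie in (0, 1)")
  }
  structure(list(
    image_path = image_path, n_curves = as.integer(n_curves),
    x_start = x_start, x_end = x_end, x_increment = x_increment,
    y_start = y_start, y_end = y_end, y_increment = y_increment,
    bg_lightness_threshold = bg_lightness_threshold,
    dark_threshold = dark_threshold, ocr_enabled = isTRUE(ocr_enabled),
    knn_k = as.integer(knn_k), hue_boost = hue_boost,
    light_boost = light_boost,
    drop_dark_censor_marks = isTRUE(drop_dark_censor_marks),
    seed = as.integer(seed), gap_horizon_frac = gap_horizon_frac,
    output_path = output_path
  ), class = "kmPipelineConfig")
}

.stage <- function(name, hint, expr) {
  tryCatch(expr, kmdigitizeError = function(e) {
    kmStop(class(e)[1], "stage '%s' failed: %s (%s)",
           name, conditionMessage(e), hint)
  })
}

#' Run the end-to-end Kaplan-Meier digitization pipeline
#'
#' Executes image loading, axis detection, background/text cleaning,
#' colour clustering, path tracing, calibration and aggregation on one
#' plot image. Identical configuration and image give byte-identical
#' output (all randomness is seeded).
#'
#' @param config a `kmPipelineConfig` from [pipelineConfig()].
#' @return list with `curves` (the long table `id`, `time`, `St`, `curve`),
#'   and `report`: per-stage pixel counts, cluster sizes and medoids, and
#'   accumulated warnings. When `output_path` is set the curve table is
#'   also written there as CSV.
#' @export
runPipeline <- function(config) {
  if (!inherits(config, "kmPipelineConfig")) {
    kmStop("kmConfigError", "config must come from pipelineConfig()")
  }
  warnings <- character(0)
  res <- withCallingHandlers({
    grid <- .stage("load", "check the image file", loadImage(config$image_path))
    axes <- .stage("axes", "clean the image background",
                   detectAxes(grid, dark_threshold = config$dark_threshold))
    mask <- .stage("clean", "lower bg_lightness_threshold",
                   removeBackground(grid, axes,
                                    light_threshold = config$bg_lightness_threshold))
    nBg <- nrow(mask@pixels)
    mask <- .stage("text", "disable OCR or install tesseract",
                   removeText(mask, ocr_enabled = config$ocr_enabled,
                              dark_threshold = config$dark_threshold))
    clusters <- .stage("cluster", "adjust hue_boost/light_boost",
                       clusterPixels(mask, config$n_curves,
                                     hue_boost = config$hue_boost,
                                     light_boost = config$light_boost,
                                     drop_dark = config$drop_dark_censor_marks,
                                     seed = config$seed,
                                     dark_threshold = config$dark_threshold))
    sizes <- as.integer(table(clusters@pixels$label))
    if (any(sizes < 0.02 * max(sizes))) {
      kmWarn("kmSmallClusterWarning",
             "a curve cluster holds under 2%% of the largest cluster's pixels")
    }
    calib <- .stage("calibrate", "check declared axis ranges",
                    calibrateAxes(grid, axes,
                                  config$x_start, config$x_end, config$x_increment,
                                  config$y_start, config$y_end, config$y_increment,
                                  ocr_enabled = config$ocr_enabled))
    curves <- lapply(seq_len(config$n_curves), function(k) {
      path <- .stage("trace", "check n_curves and image quality",
                     tracePath(clusters, k, knn_k = config$knn_k,
                               gap_horizon_frac = config$gap_horizon_frac))
      .stage("map", "check declared axis ranges",
             mapToUnits(path, calib, axes))
    })
    tab <- aggregateCurves(curves)
    list(
      curves = tab,
      report = list(
        image = config$image_path,
        imageSize = c(width = grid@width, height = grid@height),
        plotRegion = axes@plotRegion,
        pixelsAfterBackground = nBg,
        pixelsAfterText = nrow(mask@pixels),
        clusterSizes = sizes,
        medoids = clusters@medoids,
        calibration = c(xUnitsPerPx = calib@xUnitsPerPx,
                        yUnitsPerPx = calib@yUnitsPerPx)
      )
    )
  }, kmdigitizeWarning = function(w) {
    warnings <<- c(warnings, paste0(class(w)[1], ": ", conditionMessage(w)))
    invokeRestart("muffleWarning")
  })
  res$report$warnings <- warnings
  if (!is.null(config$output_path)) {
    write.csv(res$curves, config$output_path, row.names = FALSE)
  }
  res
}
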