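## Axis calibration and unit mapping.
##
## The user-declared axis ranges are authoritative; the image only
## supplies the pixel geometry. Tick marks are short dark runs in a band
## just outside the plot region; the pixel spacing between adjacent ticks
## together with the declared increment fixes the units-per-pixel "step
## size" on each axis. OCR, when enabled and available, merely verifies
## the declared ranges against recognized tick labels.

.tickCenters <- function(counts, min_len) {
  on <- which(counts >= min_len)
  if (length(on) == 0L) return(numeric(0))
  brk <- c(0L, which(diff(on) > 1L), length(on))
  vapply(seq_len(length(brk) - 1L), function(i) {
    mean(on[(brk[i] + 1L):brk[i + 1L]])
  }, numeric(1))
}

#' Calibrate pixel coordinates against declared axis ranges
#'
#' Locates tick marks as short dark runs perpendicular to each axis just
#' outside the plot region (a band of `tick_band` pixels, runs of at least
#' `min_tick_len` dark pixels). The extreme ticks anchor the declared
#' (start, end) values, fixing the units-per-pixel "step size"; when all
#' declared ticks are detected this equals the declared increment over
#' the adjacent-tick pixel spacing, and when some are missed it stays
#' correct under the two-point linear map (a tick-count warning is
#' logged). When fewer than two ticks are found on an axis, the axis is
#' calibrated by mapping the plot region's full pixel extent onto
#' (start, end), with a warning.
#'
#' @param grid a [PixelGrid-class].
#' @param axes an [AxesGeometry-class].
#' @param x_start,x_end,x_increment declared time axis range and tick
#'   increment.
#' @param y_start,y_end,y_increment declared probability axis range and
#'   tick increment.
#' @param ocr_enabled verify tick labels by OCR when an engine is
#'   available; mismatches warn, they never override the declared ranges.
#' @param tick_band width in pixels of the search band outside each axis
#'   (default 15).
#' @param min_tick_len minimal dark run length for a tick (default 3).
#' @param dark_threshold lightness cutoff for tick pixels (default 0.2).
#' @return An [AxisCalibration-class].
#' @export
calibrateAxes <- function(grid, axes, x_start, x_end, x_increment,
                          y_start, y_end, y_increment,
                          ocr_enabled = FALSE, tick_band = 15L,
                          min_tick_len = 3L, dark_threshold = 0.2) {
  stopifnot(is(grid, "PixelGrid"), is(axes, "AxesGeometry"))
  if (x_increment <= 0 || y_increment <= 0) {
    kmStop("kmInputError", "axis increments must be positive")
  }
  r <- axes@plotRegion
  dark <- grid@lightness <= dark_threshold

  # y ticks: dark runs in the band left of the vertical axis line; only
  # rows above the x axis line can carry ticks (the axis line itself and
  # anything below it must not register)
  bcols <- max(1L, axes@yAxisCol - as.integer(tick_band)):max(1L, axes@yAxisCol - 1L)
  yCounts <- rowSums(dark[, bcols, drop = FALSE])
  yCounts[axes@xAxisRow:grid@height] <- 0
  yTicks <- .tickCenters(yCounts, min_tick_len)
  nyExp <- round((y_end - y_start) / y_increment) + 1L
  if (length(yTicks) >= 2L) {
    if (length(yTicks) != nyExp) {
      kmWarn("kmTickCountWarning",
             "found %d y ticks where %d were declared; anchoring the extremes",
             length(yTicks), nyExp)
    }
    # extreme ticks anchor the declared (start, end); with all ticks
    # present this equals increment / adjacent-tick spacing
    yUnitsPerPx <- (y_end - y_start) / (max(yTicks) - min(yTicks))
    yOriginPx <- max(yTicks)  # bottom tick carries the declared start value
  } else {
    kmWarn("kmTickFallbackWarning",
           "fewer than 2 y ticks found; mapping plot extent onto declared range")
    yOriginPx <- as.numeric(r["rowMax"])
    yUnitsPerPx <- (y_end - y_start) / (r["rowMax"] - r["rowMin"])
  }

  # x ticks: dark runs in the band below the horizontal axis line, right
  # of the y axis line
  brows <- min(grid@height, axes@xAxisRow + 1L):min(grid@height, axes@xAxisRow + as.integer(tick_band))
  xCounts <- colSums(dark[brows, , drop = FALSE])
  xCounts[1:axes@yAxisCol] <- 0
  xTicks <- .tickCenters(xCounts, min_tick_len)
  nxExp <- round((x_end - x_start) / x_increment) + 1L
  if (length(xTicks) >= 2L) {
    if (length(xTicks) != nxExp) {
      kmWarn("kmTickCountWarning",
             "found %d x ticks where %d were declared; anchoring the extremes",
             length(xTicks), nxExp)
    }
    xUnitsPerPx <- (x_end - x_start) / (max(xTicks) - min(xTicks))
    xOriginPx <- min(xTicks)  # leftmost tick carries the declared start value
  } else {
    kmWarn("kmTickFallbackWarning",
           "fewer than 2 x ticks found; mapping plot extent onto declared range")
    xOriginPx <- as.numeric(r["colMin"])
    xUnitsPerPx <- (x_end - x_start) / (r["colMax"] - r["colMin"])
  }

  if (isTRUE(ocr_enabled)) {
    if (!ocrAvailable()) {
      kmWarn("kmConfigWarning",
             "OCR verification requested but no engine available; skipping")
    } else {
      .verifyTickLabels(grid, axes, xTicks, yTicks,
                        seq(x_start, x_end, by = x_increment),
                        seq(y_start, y_end, by = y_increment))
    }
  }

  new("AxisCalibration",
      xOriginPx = xOriginPx, xUnitsPerPx = xUnitsPerPx,
      yOriginPx = yOriginPx, yUnitsPerPx = yUnitsPerPx,
      declaredX = c(x_start, x_end, x_increment),
      declaredY = c(y_start, y_end, y_increment))
}

## OCR the label zone next to each tick and warn on numeric mismatches.
## Advisory only: declared ranges always win.
.verifyTickLabels <- function(grid, axes, xTicks, yTicks, xVals, yVals) {
  readZone <- function(rows, cols) {
    rows <- rows[rows >= 1 & rows <= grid@height]
    cols <- cols[cols >= 1 & cols <= grid@width]
    if (!length(rows) || !length(cols)) return(NULL)
    bmp <- grid@lightness[rows, cols, drop = FALSE] <= 0.5
    if (!any(bmp)) return(NULL)
    .tesseractRecognizer(bmp)
  }
  checkOne <- function(hit, declared) {
    if (is.null(hit)) return()
    val <- suppressWarnings(as.numeric(gsub("[^0-9.+-]", "", hit$text)))
    if (!is.na(val) && abs(val - declared) > 1e-6 * max(1, abs(declared))) {
      kmWarn("kmOcrMismatchWarning",
             "OCR read axis label %s where %g was declared", hit$text, declared)
    }
  }
  if (length(xTicks) == length(xVals)) {
    for (i in seq_along(xTicks)) {
      checkOne(readZone(axes@xAxisRow + 16:48,
                        round(xTicks[i]) + (-30:30)), xVals[i])
    }
  }
  if (length(yTicks) == length(yVals)) {
    for (i in seq_along(yTicks)) {
      checkOne(readZone(round(yTicks[i]) + (-12:12),
                        max(1, axes@yAxisCol - 70):max(1, axes@yAxisCol - 16)),
               rev(yVals)[i])
    }
  }
}

#' Map a traced pixel path to time and survival units
#'
#' Collapses the staircase to one pixel per column (the bottom-most, i.e.
#' the post-drop level, matching Kaplan-Meier right-continuity), converts
#' columns to time and rows to survival with the calibration, and
#' compresses runs of equal survival so that only step changes plus the
#' first and last column remain. Tiny negative times arising from
#' axis-line thickness (within one pixel-width of zero) are snapped to 0.
#'
#' @param path a [TracedPath-class].
#' @param calib an [AxisCalibration-class].
#' @param axes the [AxesGeometry-class] of the same image (used for
#'   sanity bounds).
#' @return A [DigitizedCurve-class].
#' @export
mapToUnits <- function(path, calib, axes) {
  stopifnot(is(path, "TracedPath"), is(calib, "AxisCalibration"))
  s <- path@steps
  if (nrow(s) == 0L) kmStop("kmInputError", "empty path")
  # bottom-most row per column: the path visits columns in order, and rows
  # are non-decreasing, so the last occurrence of each column is its lowest
  keep <- !duplicated(s[, 1L], fromLast = TRUE)
  cols <- s[keep, 1L]; rows <- s[keep, 2L]
  tm <- (cols - calib@xOriginPx) * calib@xUnitsPerPx + calib@declaredX[1]
  St <- (calib@yOriginPx - rows) * calib@yUnitsPerPx + calib@declaredY[1]
  if (any(St < -0.02 | St > 1.02)) {
    kmStop("kmCalibrationError", paste(
      "mapped survival outside [-0.02, 1.02]",
      "(likely axis misdetection); check the image and declared ranges"
    ))
  }
  tm[abs(tm) < calib@xUnitsPerPx] <- 0
  ord <- order(tm)
  tm <- tm[ord]; St <- St[ord]
  dup <- duplicated(tm)
  tm <- tm[!dup]; St <- St[!dup]
  m <- length(tm)
  keepPt <- c(TRUE, diff(St) != 0)
  keepPt[m] <- TRUE
  new("DigitizedCurve", curveId = path@curveId,
      points = data.frame(time = tm[keepPt], St = St[keepPt]))
}

#' Aggregate digitized curves into the long output table
#'
#' @param curves list of [DigitizedCurve-class] objects.
#' @return data.frame with columns `id` (sequential within curve), `time`,
#'   `St`, `curve`, sorted by (curve, time).
#' @export
aggregateCurves <- function(curves) {
  if (length(curves) == 0L) {
    kmStop("kmInputError", "no digitized curves to aggregate")
  }
  out <- do.call(rbind, lapply(curves, function(cv) {
    stopifnot(is(cv, "DigitizedCurve"))
    p <- cv@points[order(cv@points$time), , drop = FALSE]
    data.frame(id = seq_len(nrow(p)), time = p$time, St = p$St,
               curve = cv@curveId)
  }))
  out <- out[order(out$curve, out$time), , drop = FALSE]
  rownames(out) <- NULL
  out
}
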