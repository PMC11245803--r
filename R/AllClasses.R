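#' @import methods
#' @importFrom stats cor median sd rexp runif setNames
#' @importFrom utils head tail write.csv read.csv read.delim
NULL

## Central S4 containers for the digitization pipeline.
## Image coordinates are (col, row) with row 1 at the TOP of the image;
## conversion to plot coordinates (y increasing upward) happens once, in
## mapToUnits().

#' PixelGrid: an image in hue-saturation-lightness space
#'
#' Per-pixel HSL representation of a raster plot image. Hue is stored as a
#' fraction of the full hue circle in [0, 1); saturation and lightness are
#' in [0, 1]. Grayscale sources carry hue = 0 and saturation = 0 everywhere.
#'
#' @slot width image width in pixels.
#' @slot height image height in pixels.
#' @slot hue,saturation,lightness numeric matrices of dimension
#'   (height, width); row 1 is the top scanline.
#'
#' @seealso [loadImage()] which constructs a `PixelGrid` from a PNG or JPEG
#'   file, and [rgbToHsl()] for the channel conversion.
#' @export
setClass("PixelGrid",
  representation(
    width = "integer", height = "integer",
    hue = "matrix", saturation = "matrix", lightness = "matrix"
  )
)

setValidity("PixelGrid", function(object) {
  d <- c(object@height, object@width)
  if (any(d < 1L)) return("image must have positive width and height")
  for (ch in c("hue", "saturation", "lightness")) {
    m <- slot(object, ch)
    if (!all(dim(m) == d)) {
      return(sprintf("%s matrix must be %d x %d", ch, d[1], d[2]))
    }
    if (!all(is.finite(m))) return(sprintf("%s contains non-finite values", ch))
  }
  if (any(object@hue < 0 | object@hue >= 1)) return("hue must lie in [0, 1)")
  if (any(object@saturation < 0 | object@saturation > 1)) {
    return("saturation must lie in [0, 1]")
  }
  if (any(object@lightness < 0 | object@lightness > 1)) {
    return("lightness must lie in [0, 1]")
  }
  TRUE
})

setMethod("show", "PixelGrid", function(object) {
  cat(sprintf(
    "PixelGrid: %d x %d pixels (mean lightness %.3f, %s)\n",
    object@width, object@height, mean(object@lightness),
    if (all(object@saturation == 0)) "grayscale" else "colour"
  ))
})

#' AxesGeometry: detected axis lines and plot region
#'
#' Pixel positions of the y (vertical) and x (horizontal) axis lines and the
#' interior plot rectangle they bound (left and bottom respectively, under
#' the row-1-at-top convention).
#'
#' @slot yAxisCol pixel column of the vertical axis line.
#' @slot xAxisRow pixel row of the horizontal axis line.
#' @slot plotRegion named integer vector `(colMin, colMax, rowMin, rowMax)`
#'   of the interior plot rectangle, in image coordinates.
#'
#' @seealso [detectAxes()]
#' @export
setClass("AxesGeometry",
  representation(
    yAxisCol = "integer", xAxisRow = "integer", plotRegion = "integer"
  )
)

setValidity("AxesGeometry", function(object) {
  pr <- object@plotRegion
  if (length(pr) != 4L ||
      !identical(names(pr), c("colMin", "colMax", "rowMin", "rowMax"))) {
    return("plotRegion must be named (colMin, colMax, rowMin, rowMax)")
  }
  if (pr["colMin"] > pr["colMax"] || pr["rowMin"] > pr["rowMax"]) {
    return("plotRegion is empty")
  }
  if (object@yAxisCol > pr["colMin"]) {
    return("y axis line must lie at or left of the plot region")
  }
  if (object@xAxisRow < pr["rowMax"]) {
    return("x axis line must lie at or below the plot region")
  }
  TRUE
})

setMethod("show", "AxesGeometry", function(object) {
  pr <- object@plotRegion
  cat(sprintf(
    "AxesGeometry: y axis at col %d, x axis at row %d; plot region cols %d-%d, rows %d-%d\n",
    object@yAxisCol, object@xAxisRow,
    pr["colMin"], pr["colMax"], pr["rowMin"], pr["rowMax"]
  ))
})

#' CurvePixelMask: candidate curve pixels after background cleaning
#'
#' Retained pixels inside the plot region, each with its HSL triple, after
#' white/light-gray background removal (and, optionally, text removal).
#'
#' @slot pixels data.frame with columns `col`, `row`, `hue`, `saturation`,
#'   `lightness`; one row per retained pixel.
#' @slot region the plot rectangle the pixels were taken from (same layout
#'   as `plotRegion` of [AxesGeometry-class]).
#'
#' @seealso [removeBackground()], [removeText()]
#' @export
setClass("CurvePixelMask",
  representation(pixels = "data.frame", region = "integer")
)

setValidity("CurvePixelMask", function(object) {
  px <- object@pixels
  need <- c("col", "row", "hue", "saturation", "lightness")
  if (!all(need %in% names(px))) {
    return(paste("pixels must have columns", paste(need, collapse = ", ")))
  }
  r <- object@region
  if (nrow(px) > 0) {
    if (any(px$col < r["colMin"] | px$col > r["colMax"] |
            px$row < r["rowMin"] | px$row > r["rowMax"])) {
      return("mask pixels outside the plot region")
    }
  }
  TRUE
})

setMethod("show", "CurvePixelMask", function(object) {
  cat(sprintf(
    "CurvePixelMask: %d pixels in region cols %d-%d, rows %d-%d\n",
    nrow(object@pixels), object@region["colMin"], object@region["colMax"],
    object@region["rowMin"], object@region["rowMax"]
  ))
})

#' CurveClusterSet: pixel-to-curve assignment from colour clustering
#'
#' @slot pixels data.frame as in [CurvePixelMask-class] plus an integer
#'   `label` column in 1..nCurves.
#' @slot medoids numeric matrix (nCurves x 3) of medoid HSL triples, one row
#'   per curve label, on the original (un-boosted) scale.
#' @slot region plot rectangle, as in [CurvePixelMask-class].
#'
#' @seealso [clusterPixels()]
#' @export
setClass("CurveClusterSet",
  representation(pixels = "data.frame", medoids = "matrix", region = "integer")
)

setValidity("CurveClusterSet", function(object) {
  px <- object@pixels
  if (!"label" %in% names(px)) return("pixels must carry a label column")
  k <- nrow(object@medoids)
  if (k < 1L) return("needs at least one medoid")
  if (nrow(px) > 0) {
    if (any(!px$label %in% seq_len(k))) return("labels outside 1..nCurves")
    if (!all(seq_len(k) %in% px$label)) return("empty cluster present")
  }
  TRUE
})

setMethod("show", "CurveClusterSet", function(object) {
  tab <- table(object@pixels$label)
  cat(sprintf(
    "CurveClusterSet: %d curves over %d pixels (sizes: %s)\n",
    nrow(object@medoids), nrow(object@pixels),
    paste(as.integer(tab), collapse = ", ")
  ))
})

#' TracedPath: a single-pixel-wide monotone staircase for one curve
#'
#' Consecutive steps differ by exactly (+1, 0) (one column right) or
#' (0, +1) (one row down, i.e. towards lower survival).
#'
#' @slot curveId integer curve label.
#' @slot steps integer matrix (n x 2) with columns `col`, `row`, ordered
#'   along the trace.
#'
#' @seealso [tracePath()]
#' @export
setClass("TracedPath", representation(curveId = "integer", steps = "matrix"))

setValidity("TracedPath", function(object) {
  s <- object@steps
  if (ncol(s) != 2L) return("steps must have two columns (col, row)")
  if (nrow(s) > 1) {
    dc <- diff(s[, 1]); dr <- diff(s[, 2])
    ok <- (dc == 1L & dr == 0L) | (dc == 0L & dr == 1L)
    if (!all(ok)) return("steps must move one pixel right or one pixel down")
  }
  TRUE
})

setMethod("show", "TracedPath", function(object) {
  cat(sprintf(
    "TracedPath: curve %d, %d steps, cols %d-%d\n",
    object@curveId, nrow(object@steps),
    min(object@steps[, 1]), max(object@steps[, 1])
  ))
})

#' AxisCalibration: pixel-to-unit mapping for both axes
#'
#' @slot xOriginPx pixel column of time = declared x start.
#' @slot xUnitsPerPx time units per pixel (> 0).
#' @slot yOriginPx pixel row of probability = declared y start.
#' @slot yUnitsPerPx probability per pixel (> 0, applied upward).
#' @slot declaredX,declaredY numeric `(start, end, increment)` for each axis.
#'
#' @seealso [calibrateAxes()], [mapToUnits()]
#' @export
setClass("AxisCalibration",
  representation(
    xOriginPx = "numeric", xUnitsPerPx = "numeric",
    yOriginPx = "numeric", yUnitsPerPx = "numeric",
    declaredX = "numeric", declaredY = "numeric"
  )
)

setValidity("AxisCalibration", function(object) {
  if (object@xUnitsPerPx <= 0 || object@yUnitsPerPx <= 0) {
    return("units-per-pixel must be positive on both axes")
  }
  for (ax in c("declaredX", "declaredY")) {
    d <- slot(object, ax)
    if (length(d) != 3L) return(sprintf("%s must be (start, end, increment)", ax))
    if (d[3] <= 0) return(sprintf("%s increment must be positive", ax))
    nsteps <- (d[2] - d[1]) / d[3]
    if (nsteps <= 0 || abs(nsteps - round(nsteps)) > 1e-6) {
      return(sprintf("%s range must be a positive whole number of increments", ax))
    }
  }
  TRUE
})

setMethod("show", "AxisCalibration", function(object) {
  cat(sprintf(
    "AxisCalibration: x %.4g units/px from col %.1f; y %.4g units/px from row %.1f\n",
    object@xUnitsPerPx, object@xOriginPx, object@yUnitsPerPx, object@yOriginPx
  ))
})

#' DigitizedCurve: calibrated step points for one curve
#'
#' @slot curveId integer curve label.
#' @slot points data.frame with columns `time` (strictly increasing) and
#'   `St` (non-increasing survival probability), holding only step changes
#'   plus the first and last digitized column.
#'
#' @seealso [mapToUnits()], [aggregateCurves()]
#' @export
setClass("DigitizedCurve", representation(curveId = "integer", points = "data.frame"))

setValidity("DigitizedCurve", function(object) {
  p <- object@points
  if (!all(c("time", "St") %in% names(p))) {
    return("points must have columns time, St")
  }
  if (nrow(p) > 1) {
    if (any(diff(p$time) <= 0)) return("times must be strictly increasing")
    if (any(diff(p$St) > 1e-9)) return("survival must be non-increasing")
  }
  if (nrow(p) > 0 && (min(p$St) < -0.021 || max(p$St) > 1.021)) {
    return("survival outside [0, 1] beyond half-pixel tolerance")
  }
  TRUE
})

setMethod("show", "DigitizedCurve", function(object) {
  p <- object@points
  cat(sprintf(
    "DigitizedCurve: curve %d, %d step points, time %.3g-%.3g, S %.3f-%.3f\n",
    object@curveId, nrow(p), min(p$time), max(p$time), max(p$St), min(p$St)
  ))
})

#' StepFunction: a right-continuous survival step function
#'
#' Knots `time` with survival levels `surv`; evaluation between knots is
#' right-continuous (the level at the largest knot at or before t applies).
#'
#' @slot time increasing numeric knot times.
#' @slot surv numeric survival levels at the knots, non-increasing.
#'
#' @seealso [stepFunction()], [kmEstimate()], [remapProbability()]
#' @export
setClass("StepFunction", representation(time = "numeric", surv = "numeric"))

setValidity("StepFunction", function(object) {
  if (length(object@time) != length(object@surv)) {
    return("time and surv must have equal length")
  }
  if (length(object@time) == 0L) return("step function needs at least one knot")
  if (any(diff(object@time) < 0)) return("knot times must be non-decreasing")
  if (any(diff(object@surv) > 1e-9)) return("survival must be non-increasing")
  TRUE
})

setMethod("show", "StepFunction", function(object) {
  cat(sprintf(
    "StepFunction: %d knots, time %.3g-%.3g, S %.3f-%.3f\n",
    length(object@time), min(object@time), max(object@time),
    max(object@surv), min(object@surv)
  ))
})

#' Construct a survival step function
#'
#' @param time increasing numeric knot times.
#' @param surv survival levels at the knots (non-increasing).
#' @return A [StepFunction-class] object.
#' @examples
#' stepFunction(c(0, 10, 20), c(1, 0.6, 0.2))
#' @export
stepFunction <- function(time, surv) {
  new("StepFunction", time = as.numeric(time), surv = as.numeric(surv))
}

## ---- accessors ----

#' Accessors for pipeline objects
#'
#' `curveId()` returns the curve label of a traced path or digitized curve;
#' `curvePoints()` the (time, St) data.frame of a digitized curve;
#' `maskPixels()` the pixel data.frame of a mask or cluster set;
#' `plotRegion()` the plot rectangle of an axes geometry, mask, or cluster
#' set; `stepTimes()` / `stepSurv()` the knots of a step function;
#' `clusterMedoids()` the medoid HSL matrix of a cluster set.
#'
#' @param x the object.
#' @return The slot contents, never the raw slot: use these rather than `@`.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("curveId", function(x) standardGeneric("curveId"))
#' @rdname accessors
#' @export
setMethod("curveId", "TracedPath", function(x) x@curveId)
#' @rdname accessors
#' @export
setMethod("curveId", "DigitizedCurve", function(x) x@curveId)

#' @rdname accessors
#' @export
setGeneric("curvePoints", function(x) standardGeneric("curvePoints"))
#' @rdname accessors
#' @export
setMethod("curvePoints", "DigitizedCurve", function(x) x@points)

#' @rdname accessors
#' @export
setGeneric("maskPixels", function(x) standardGeneric("maskPixels"))
#' @rdname accessors
#' @export
setMethod("maskPixels", "CurvePixelMask", function(x) x@pixels)
#' @rdname accessors
#' @export
setMethod("maskPixels", "CurveClusterSet", function(x) x@pixels)

#' @rdname accessors
#' @export
setGeneric("plotRegion", function(x) standardGeneric("plotRegion"))
#' @rdname accessors
#' @export
setMethod("plotRegion", "AxesGeometry", function(x) x@plotRegion)
#' @rdname accessors
#' @export
setMethod("plotRegion", "CurvePixelMask", function(x) x@region)
#' @rdname accessors
#' @export
setMethod("plotRegion", "CurveClusterSet", function(x) x@region)

#' @rdname accessors
#' @export
setGeneric("stepTimes", function(x) standardGeneric("stepTimes"))
#' @rdname accessors
#' @export
setMethod("stepTimes", "StepFunction", function(x) x@time)

#' @rdname accessors
#' @export
setGeneric("stepSurv", function(x) standardGeneric("stepSurv"))
#' @rdname accessors
#' @export
setMethod("stepSurv", "StepFunction", function(x) x@surv)

#' @rdname accessors
#' @export
setGeneric("clusterMedoids", function(x) standardGeneric("clusterMedoids"))
#' @rdname accessors
#' @export
setMethod("clusterMedoids", "CurveClusterSet", function(x) x@medoids)

#' @rdname accessors
#' @export
setGeneric("pathSteps", function(x) standardGeneric("pathSteps"))
#' @rdname accessors
#' @export
setMethod("pathSteps", "TracedPath", function(x) x@steps)

## internal error helpers: every user-facing failure carries a stage class
kmStop <- function(class, fmt, ...) {
  msg <- if (...length() == 0L) fmt else sprintf(fmt, ...)
  stop(structure(
    class = c(class, "kmdigitizeError", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

kmWarn <- function(class, fmt, ...) {
  msg <- if (...length() == 0L) fmt else sprintf(fmt, ...)
  warning(structure(
    class = c(class, "kmdigitizeWarning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
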