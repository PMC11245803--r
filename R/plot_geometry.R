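## Axis detection and plot cleaning.
##
## Axis lines are found by counting dark pixels (lightness <= dark
## threshold) along every row and column of the raw grid: the vertical and
## horizontal axis lines are the column / row where that count peaks. The
## same dark band (<= 0.2) that classifies "black or dark gray" pixels for
## text/censor-mark handling is reused here; visibly coloured pixels fall
## in (0.2, 0.8) and the white background at >= 0.8.

#' Detect the x and y axis lines and the plot region
#'
#' Counts pixels with lightness at or below `dark_threshold` along each
#' column and row. The y axis is the column with the maximal dark count
#' (ties broken towards the leftmost column, so the left edge of a framed
#' box wins); the x axis is the row with the maximal count (ties towards
#' the bottommost row). A column/row only qualifies when its dark count
#' reaches `min_run_frac` of the image dimension, which rejects dense text
#' lines. The plot region is the rectangle to the right of the vertical
#' axis line run and above the horizontal one, shrunk inward by
#' `region_inset` pixels to step over compression ringing that hugs the
#' axis lines.
#'
#' @param grid a [PixelGrid-class].
#' @param dark_threshold lightness cutoff defining "black" pixels
#'   (default 0.2).
#' @param min_run_frac minimal fraction of the dimension a candidate axis
#'   line must cover (default 0.5).
#' @param region_inset pixels trimmed from the region edge adjacent to each
#'   axis line (default 4, about the reach of JPEG ringing from a dark line).
#' @return An [AxesGeometry-class].
#' @examples
#' L <- matrix(1, 300, 400); L[, 40] <- 0; L[260, ] <- 0
#' g <- new("PixelGrid", width = 400L, height = 300L,
#'          hue = L * 0, saturation = L * 0, lightness = L)
#' detectAxes(g)
#' @export
detectAxes <- function(grid, dark_threshold = 0.2, min_run_frac = 0.5,
                       region_inset = 4L) {
  stopifnot(is(grid, "PixelGrid"))
  if (dark_threshold <= 0 || dark_threshold >= 1) {
    kmStop("kmInputError", "dark_threshold must lie in (0, 1)")
  }
  dark <- grid@lightness <= dark_threshold
  colCounts <- colSums(dark)
  rowCounts <- rowSums(dark)
  h <- grid@height; w <- grid@width
  if (max(colCounts) < min_run_frac * h || max(rowCounts) < min_run_frac * w) {
    kmStop("kmAxesError", paste(
      "axes not found: no row/column holds a dark-pixel run covering",
      sprintf("%d%% of the plot;", round(100 * min_run_frac)),
      "clean the image (remove dark grids/frames) and retry"
    ))
  }
  yAxisCol <- which.max(colCounts)                   # first max = leftmost
  xs <- which(rowCounts == max(rowCounts))
  xAxisRow <- xs[length(xs)]                         # last max = bottommost
  # the axis line may be several pixels thick: walk along the contiguous
  # qualifying run before starting the region
  cc <- yAxisCol
  while (cc + 1L <= w && colCounts[cc + 1L] >= min_run_frac * h) cc <- cc + 1L
  rr <- xAxisRow
  while (rr - 1L >= 1L && rowCounts[rr - 1L] >= min_run_frac * w) rr <- rr - 1L
  colMin <- cc + 1L + as.integer(region_inset)
  rowMax <- rr - 1L - as.integer(region_inset)
  if (colMin > w || rowMax < 1L) {
    kmStop("kmAxesError", "axes leave no plot region; check the image")
  }
  new("AxesGeometry",
      yAxisCol = as.integer(yAxisCol), xAxisRow = as.integer(xAxisRow),
      plotRegion = c(colMin = as.integer(colMin), colMax = as.integer(w),
                     rowMin = 1L, rowMax = as.integer(rowMax)))
}

.asRegion <- function(region) {
  if (is(region, "AxesGeometry")) return(region@plotRegion)
  r <- as.integer(region)
  names(r) <- c("colMin", "colMax", "rowMin", "rowMax")
  r
}

#' Remove background and gridline pixels
#'
#' Keeps only pixels inside the plot region whose lightness is strictly
#' below `light_threshold`: pixels at or above it are considered white
#' background or very light gray gridlines. Axis-line pixels are excluded
#' because they lie outside the region.
#'
#' @param grid a [PixelGrid-class].
#' @param region an [AxesGeometry-class] or a named integer vector
#'   `(colMin, colMax, rowMin, rowMax)`.
#' @param light_threshold lightness at or above which a pixel counts as
#'   background (default 0.8).
#' @return A [CurvePixelMask-class] carrying the retained pixels and their
#'   HSL triples.
#' @export
removeBackground <- function(grid, region, light_threshold = 0.8) {
  stopifnot(is(grid, "PixelGrid"))
  if (light_threshold <= 0 || light_threshold > 1) {
    kmStop("kmInputError", "light_threshold must lie in (0, 1]")
  }
  r <- .asRegion(region)
  rows <- r["rowMin"]:r["rowMax"]
  cols <- r["colMin"]:r["colMax"]
  sub <- grid@lightness[rows, cols, drop = FALSE]
  keep <- which(sub < light_threshold, arr.ind = TRUE)
  if (nrow(keep) == 0L) {
    kmStop("kmCleanError",
           "no curve pixels remain after background removal; lower light_threshold?")
  }
  prow <- rows[keep[, 1]]
  pcol <- cols[keep[, 2]]
  ij <- cbind(prow, pcol)
  px <- data.frame(
    col = as.integer(pcol), row = as.integer(prow),
    hue = grid@hue[ij], saturation = grid@saturation[ij],
    lightness = grid@lightness[ij]
  )
  new("CurvePixelMask", pixels = px, region = r)
}

## Render a pixel component to an upscaled PNG and ask the tesseract CLI
## what it reads. Returns list(text, confidence) or NULL when unreadable.
.tesseractRecognizer <- function(bitmap) {
  exe <- Sys.which("tesseract")
  if (!nzchar(exe)) return(NULL)
  scale <- 4L
  big <- kronecker(1 - bitmap, matrix(1, scale, scale))  # ink = 0 (black)
  f <- tempfile(fileext = ".png")
  on.exit(unlink(c(f, paste0(f, ".tsv"))), add = TRUE)
  png::writePNG(big, f)
  out <- suppressWarnings(system2(
    exe, c(shQuote(f), "stdout", "--psm", "8", "tsv"),
    stdout = TRUE, stderr = FALSE
  ))
  tsv <- tryCatch(
    read.delim(text = paste(out, collapse = "\n"), stringsAsFactors = FALSE),
    error = function(e) NULL
  )
  if (is.null(tsv) || !all(c("conf", "text") %in% names(tsv))) return(NULL)
  words <- tsv[tsv$conf >= 0 & nzchar(trimws(tsv$text)), , drop = FALSE]
  if (nrow(words) == 0L) return(NULL)
  best <- words[which.max(words$conf), ]
  list(text = trimws(best$text), confidence = as.numeric(best$conf))
}

#' Whether an OCR engine is available to the package
#'
#' The default recognizer shells out to a `tesseract` binary; this reports
#' whether one is on the PATH.
#' @return logical flag.
#' @export
ocrAvailable <- function() nzchar(Sys.which("tesseract"))

#' Remove text rendered inside the plot region
#'
#' Groups dark pixels (lightness at or below `dark_threshold`) into
#' connected components (after a small dilation that merges the glyphs of
#' one word), submits each component to a character recognizer, and deletes
#' components recognized as purely alphabetic words of length at least two
#' with confidence at or above `confidence`. Numerals and symbols are left
#' in place -- stray p-values overlapping a curve are the user's manual
#' clean-up responsibility.
#'
#' @param mask a [CurvePixelMask-class].
#' @param ocr_enabled when `FALSE` the mask is returned unchanged.
#' @param recognizer a function taking a logical glyph bitmap (TRUE = ink)
#'   and returning `list(text =, confidence =)` or `NULL`; defaults to a
#'   tesseract-CLI recognizer when a `tesseract` binary is on the PATH.
#' @param confidence recognition confidence floor on a 0-100 scale
#'   (default 60).
#' @param dark_threshold lightness cutoff for text pixels (default 0.2).
#' @return A [CurvePixelMask-class] without the recognized word pixels.
#' @export
removeText <- function(mask, ocr_enabled = TRUE, recognizer = NULL,
                       confidence = 60, dark_threshold = 0.2) {
  stopifnot(is(mask, "CurvePixelMask"))
  if (!isTRUE(ocr_enabled)) return(mask)
  if (is.null(recognizer)) {
    if (!ocrAvailable()) {
      kmStop("kmConfigError", paste(
        "OCR is enabled but no OCR engine is available;",
        "set ocr_enabled = FALSE or install the tesseract binary"
      ))
    }
    recognizer <- .tesseractRecognizer
  }
  px <- mask@pixels
  darkIdx <- which(px$lightness <= dark_threshold)
  if (length(darkIdx) == 0L) return(mask)
  r <- mask@region
  H <- r["rowMax"] - r["rowMin"] + 1L
  W <- r["colMax"] - r["colMin"] + 1L
  bin <- matrix(0L, H, W)
  bin[cbind(px$row[darkIdx] - r["rowMin"] + 1L,
            px$col[darkIdx] - r["colMin"] + 1L)] <- 1L
  # merge glyphs of one word before labelling
  merged <- EBImage::dilate(bin, EBImage::makeBrush(7, "box"))
  labels <- EBImage::bwlabel(merged)
  compOf <- labels[cbind(px$row[darkIdx] - r["rowMin"] + 1L,
                         px$col[darkIdx] - r["colMin"] + 1L)]
  drop <- logical(nrow(px))
  for (comp in unique(compOf)) {
    sel <- darkIdx[compOf == comp]
    rows <- px$row[sel]; cols <- px$col[sel]
    bmp <- matrix(FALSE, max(rows) - min(rows) + 1L, max(cols) - min(cols) + 1L)
    bmp[cbind(rows - min(rows) + 1L, cols - min(cols) + 1L)] <- TRUE
    hit <- recognizer(bmp)
    if (!is.null(hit) && grepl("^[A-Za-z]{2,}$", hit$text) &&
        hit$confidence >= confidence) {
      drop[sel] <- TRUE
    }
  }
  if (!any(drop)) return(mask)
  new("CurvePixelMask", pixels = px[!drop, , drop = FALSE], region = r)
}
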