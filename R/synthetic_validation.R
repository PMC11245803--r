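## Simulation study harness: generate censored exponential cohorts, render
## their Kaplan-Meier plots as JPEG images in two engine styles, digitize
## the images back, and score the digitization against the known truth at
## evenly spaced time checkpoints.

#' Simulate a right-censored exponential cohort
#'
#' Event times are exponential with rate `event_rate`; when censoring is
#' on, independent censoring times are exponential with rate
#' `censor_rate`, the observed time is the minimum and the status records
#' whether the event was observed. Group labels are assigned uniformly at
#' random (a conservative choice that makes the group curves overlap
#' considerably); assignment is redrawn if some group ends up empty.
#'
#' @param n number of subjects.
#' @param n_groups number of treatment arms (default 1).
#' @param censoring apply random right censoring (default TRUE).
#' @param seed RNG seed.
#' @param event_rate,censor_rate exponential hazards (defaults 0.01 and
#'   0.005, i.e. mean event time 100 and mean censoring time 200 study
#'   time units).
#' @return data.frame with columns `time`, `status` (1 event, 0 censored)
#'   and `group` (1..n_groups).
#' @export
simulateCohort <- function(n, n_groups = 1, censoring = TRUE, seed = 1,
                           event_rate = 0.01, censor_rate = 0.005) {
  if (n < 1 || n_groups < 1) {
    kmStop("kmInputError", "n and n_groups must be positive")
  }
  .withSeed(seed, {
    ev <- rexp(n, rate = event_rate)
    if (censoring) {
      cs <- rexp(n, rate = censor_rate)
      time <- pmin(ev, cs)
      status <- as.integer(ev <= cs)
    } else {
      time <- ev
      status <- rep(1L, n)
    }
    group <- sample.int(n_groups, n, replace = TRUE)
    while (n_groups > 1 && length(unique(group)) < n_groups) {
      group <- sample.int(n_groups, n, replace = TRUE)
    }
    data.frame(time = time, status = status, group = group)
  })
}

#' Product-limit (Kaplan-Meier) estimate as a step function
#'
#' Delegates to [survival::survfit()]. The returned step function starts
#' at (0, 1) and has a knot at every observed time (event or censoring),
#' so its last knot is the group's maximum study time.
#'
#' @param cohort data.frame with `time`, `status` and optionally `group`.
#' @param group when given, restrict to that group.
#' @return A [StepFunction-class].
#' @export
kmEstimate <- function(cohort, group = NULL) {
  d <- cohort
  if (!is.null(group) && "group" %in% names(d)) {
    d <- d[d$group == group, , drop = FALSE]
  }
  if (nrow(d) == 0L) kmStop("kmInputError", "empty group")
  fit <- survival::survfit(survival::Surv(time, status) ~ 1, data = d)
  stepFunction(c(0, fit$time), c(1, fit$surv))
}

## Palette: well-separated hues (red, blue, green), saturated and mid-dark
## so curve pixels sit inside the colour band (0.2, 0.8) of lightness.
.kmPalette <- function() {
  data.frame(hue = c(0, 2 / 3, 1 / 3), saturation = 0.75, lightness = 0.45)
}

#' Render Kaplan-Meier step functions as a JPEG plot image
#'
#' A deterministic rasterizer purpose-built for the validation study: it
#' draws black axis lines with tick marks, then each curve as a coloured
#' step line, and writes the image as JPEG. Two style presets are
#' provided: `style_a` mimics a base-graphics look (white background,
#' line width 3); `style_b` a gray-panel look (light-gray plot panel with
#' white grid lines, line width 5). Optional censoring marks are short
#' vertical ticks at the censoring times, drawn in the curve's own colour.
#'
#' @param functions list of 1-3 [StepFunction-class] objects (one per
#'   curve); curve `i` uses palette hue `i` (red, blue, green - separated
#'   by at least 120 degrees on the hue circle).
#' @param style `"style_a"` or `"style_b"`.
#' @param censor_marks draw censoring tick glyphs (default FALSE).
#' @param censor_times list of numeric vectors (censoring times per
#'   curve), used when `censor_marks` is TRUE.
#' @param path output JPEG file path.
#' @param region_width,region_height plot-region size in pixels
#'   (defaults 1600 x 1000).
#' @param y_axis `(start, end, increment)` of the probability axis
#'   (default `c(0, 1, 0.25)`).
#' @param x_axis `(start, end, increment)` of the time axis; by default
#'   chosen automatically as a round increment covering all curves.
#' @param quality JPEG quality in (0, 1] (default 0.95).
#' @return (invisibly) list with `path`, `x_axis`, `y_axis`, `palette`
#'   (the HSL palette rows used) and the pixel `geometry`.
#' @export
renderKMPlot <- function(functions, style = c("style_a", "style_b"),
                         censor_marks = FALSE, censor_times = list(),
                         path, region_width = 1600L, region_height = 1000L,
                         y_axis = c(0, 1, 0.25), x_axis = NULL,
                         quality = 0.95) {
  style <- match.arg(style)
  if (length(functions) < 1L || length(functions) > 3L) {
    kmStop("kmInputError", "renderKMPlot supports 1-3 curves")
  }
  tmax <- max(vapply(functions, function(f) max(f@time), numeric(1)))
  if (is.null(x_axis)) {
    pr <- pretty(c(0, tmax), n = 5)
    inc <- diff(pr)[1]
    end <- inc * max(1, ceiling(tmax / inc - 1e-9))
    x_axis <- c(0, end, inc)
  }
  mar <- switch(style,
    style_a = c(left = 90L, right = 50L, top = 40L, bottom = 70L),
    style_b = c(left = 80L, right = 36L, top = 30L, bottom = 60L)
  )
  lw <- if (style == "style_a") 1L else 2L   # half-width: total 3 or 5 px
  W <- as.integer(region_width); H <- as.integer(region_height)
  imgW <- unname(mar["left"] + W + mar["right"])
  imgH <- unname(mar["top"] + H + mar["bottom"])
  c0 <- unname(mar["left"] + 1L)  # first data column (time = x start)
  r0 <- unname(mar["top"] + 1L)   # first data row (survival = y end)
  R <- matrix(1, imgH, imgW); G <- matrix(1, imgH, imgW); B <- matrix(1, imgH, imgW)
  setPx <- function(rows, cols, rgb) {
    rows <- rows[rows >= 1 & rows <= imgH]
    cols <- cols[cols >= 1 & cols <= imgW]
    if (!length(rows) || !length(cols)) return()
    R[rows, cols] <<- rgb[1]; G[rows, cols] <<- rgb[2]; B[rows, cols] <<- rgb[3]
  }
  setIdx <- function(rows, cols, rgb) {  # paired row/col vectors
    ok <- rows >= 1 & rows <= imgH & cols >= 1 & cols <= imgW
    ij <- cbind(rows[ok], cols[ok])
    if (!nrow(ij)) return()
    R[ij] <<- rgb[1]; G[ij] <<- rgb[2]; B[ij] <<- rgb[3]
  }
  colOf <- function(t) c0 + as.integer(round((t - x_axis[1]) / (x_axis[2] - x_axis[1]) * (W - 1L)))
  rowOf <- function(v) (r0 + H - 1L) - as.integer(round((v - y_axis[1]) / (y_axis[2] - y_axis[1]) * (H - 1L)))
  xTickVals <- seq(x_axis[1], x_axis[2], by = x_axis[3])
  yTickVals <- seq(y_axis[1], y_axis[2], by = y_axis[3])

  if (style == "style_b") {
    setPx(r0:(r0 + H - 1L), c0:(c0 + W - 1L), c(0.93, 0.93, 0.93))
    for (tv in xTickVals) setPx(r0:(r0 + H - 1L), colOf(tv) + (-1:1), c(1, 1, 1))
    for (vv in yTickVals) setPx(rowOf(vv) + (-1:1), c0:(c0 + W - 1L), c(1, 1, 1))
  }
  # axis lines (3 px), separated from the data area by a 3 px gap
  yAxC <- c0 - 6L; xAxR <- r0 + H + 2L
  setPx((r0 - 8L):(xAxR + 2L), yAxC + (0:2), c(0, 0, 0))
  setPx(xAxR + (0:2), (yAxC):(c0 + W + 9L), c(0, 0, 0))
  # ticks: 3 px thick runs of length 8, outside the axis lines
  for (tv in xTickVals) setPx((xAxR + 3L):(xAxR + 10L), colOf(tv) + (-1:1), c(0, 0, 0))
  for (vv in yTickVals) setPx(rowOf(vv) + (-1:1), (yAxC - 8L):(yAxC - 1L), c(0, 0, 0))

  pal <- .kmPalette()
  for (i in seq_along(functions)) {
    f <- functions[[i]]
    rgb <- hslToRgb(pal$hue[i], pal$saturation[i], pal$lightness[i]) / 255
    fend <- colOf(min(max(f@time), x_axis[2]))
    cols <- c0:fend
    tAt <- (cols - c0) / (W - 1L) * (x_axis[2] - x_axis[1]) + x_axis[1]
    sAt <- .stepEval(f, tAt)
    # the final column carries the terminal level, so a drop at the last
    # knot is always painted even when the column time rounds below it
    if (max(f@time) <= x_axis[2]) sAt[length(sAt)] <- f@surv[length(f@surv)]
    rws <- rowOf(sAt)
    for (dy in -lw:lw) setIdx(rws + dy, cols, rgb)
    drops <- which(diff(rws) > 0)
    for (dI in drops) {
      setPx((rws[dI] - lw):(rws[dI + 1L] + lw), cols[dI + 1L] + (-lw:lw), rgb)
    }
    if (isTRUE(censor_marks) && length(censor_times) >= i) {
      for (ct in censor_times[[i]]) {
        if (ct < x_axis[1] || ct > x_axis[2] || ct > max(f@time)) next
        cc <- colOf(ct)
        rc <- rowOf(.stepEval(f, ct))
        setPx((rc - 6L):(rc + 6L), cc + (0:1), rgb)
      }
    }
  }
  img <- array(c(R, G, B), dim = c(imgH, imgW, 3L))
  jpeg::writeJPEG(img, target = path, quality = quality)
  invisible(list(
    path = path, x_axis = unname(x_axis), y_axis = unname(y_axis),
    palette = pal[seq_along(functions), , drop = FALSE],
    geometry = list(img_width = unname(imgW), img_height = unname(imgH),
                    data_col0 = unname(c0), data_row0 = unname(r0),
                    region_width = W, region_height = H)
  ))
}

## plain right-continuous evaluation (no exhaustion rule) - used when
## rendering, where the last level must persist to the last knot
.stepEval <- function(f, t) {
  idx <- findInterval(t, f@time)
  f@surv[pmax(idx, 1L)]
}

#' Evaluate a step function at a checkpoint with the study's remapping
#'
#' Right-continuous evaluation with the convention used for scoring: if
#' every knot time is at or below `t`, the curve is considered exhausted
#' and the survival is 0 (no survivors beyond the digitized range);
#' otherwise the survival at the largest knot at or below `t` applies;
#' if no knot is at or below `t` (cannot happen for curves anchored at
#' time 0, kept as a defensive branch) the value is 1.
#'
#' @param f a [StepFunction-class].
#' @param t numeric vector of checkpoint times (>= 0).
#' @return numeric vector of survival values.
#' @export
remapProbability <- function(f, t) {
  stopifnot(is(f, "StepFunction"))
  idx <- findInterval(t, f@time)
  out <- ifelse(idx == 0L, 1,
                ifelse(idx >= length(f@time) & t >= max(f@time), 0,
                       f@surv[pmax(idx, 1L)]))
  as.numeric(out)
}

#' Checkpoint RMSE between a digitized and a true survival curve
#'
#' Both functions are evaluated with [remapProbability()] at
#' `n_checkpoints` evenly spaced times from 0 to the true curve's maximum
#' study time (its last knot), inclusive; the result is the root mean
#' squared difference.
#'
#' @param digitized,truth [StepFunction-class] objects.
#' @param n_checkpoints number of checkpoints (default 100).
#' @return numeric RMSE on the survival-probability scale.
#' @export
rmseCurve <- function(digitized, truth, n_checkpoints = 100) {
  if (n_checkpoints < 2) kmStop("kmInputError", "need at least 2 checkpoints")
  cp <- seq(0, max(truth@time), length.out = n_checkpoints)
  d <- remapProbability(digitized, cp) - remapProbability(truth, cp)
  sqrt(mean(d^2))
}

#' Bland-Altman limits of agreement
#'
#' @param a,b equal-length paired probability series.
#' @return named numeric `(mean_diff, lower_limit, upper_limit)` with
#'   limits at 1.96 standard deviations (n-1 denominator) around the mean
#'   difference.
#' @export
blandAltman <- function(a, b) {
  if (length(a) != length(b)) {
    kmStop("kmInputError", "paired series must have equal length")
  }
  d <- a - b
  m <- mean(d)
  s <- if (length(d) > 1) sd(d) else 0
  c(mean_diff = m, lower_limit = m - 1.96 * s, upper_limit = m + 1.96 * s)
}

#' Kendall's tau-b between a reference and a candidate curve
#'
#' The candidate is evaluated (via [remapProbability()]) at the reference
#' curve's own time points and the tie-corrected Kendall tau-b between
#' the paired survival series is returned. A constant series on either
#' side leaves tau undefined: the function returns `NA` with a warning.
#'
#' @param reference a [StepFunction-class] whose time points serve as the
#'   pairing grid (e.g. a manual digitization).
#' @param candidate a [StepFunction-class] to compare (e.g. the automated
#'   digitization).
#' @return numeric tau in `[-1, 1]`, or `NA` when undefined.
#' @export
kendallTau <- function(reference, candidate) {
  stopifnot(is(reference, "StepFunction"), is(candidate, "StepFunction"))
  if (length(reference@time) < 2L) {
    kmStop("kmInputError", "reference needs at least 2 points")
  }
  a <- reference@surv
  b <- remapProbability(candidate, reference@time)
  if (length(unique(a)) < 2L || length(unique(b)) < 2L) {
    kmWarn("kmDegenerateSeriesWarning",
           "constant series: Kendall tau undefined")
    return(NA_real_)
  }
  unname(cor(a, b, method = "kendall"))
}

#' The full simulation scenario grid
#'
#' Crosses sample size (25, 50, 150, 250, 1000), curves per plot (1-3),
#' censoring (off/on) and the two rendering styles: 60 plots carrying 120
#' curves in total.
#'
#' @return data.frame with one row per plot: `plot_id`, `n`, `n_curves`,
#'   `censoring`, `style`.
#' @export
scenarioGrid <- function() {
  g <- expand.grid(
    n = c(25L, 50L, 150L, 250L, 1000L),
    n_curves = 1:3,
    censoring = c(FALSE, TRUE),
    style = c("style_a", "style_b"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  g <- g[order(g$style, g$censoring, g$n_curves, g$n), , drop = FALSE]
  rownames(g) <- NULL
  cbind(plot_id = seq_len(nrow(g)), g)
}

## Match digitized curves to simulated groups by medoid hue against the
## rendering palette (cluster labels are ordered by hue, group colours
## are not).
.matchCurvesToGroups <- function(medoids, n_groups) {
  pal <- .kmPalette()$hue[seq_len(n_groups)]
  used <- logical(n_groups)
  map <- integer(nrow(medoids))
  for (i in seq_len(nrow(medoids))) {
    dh <- abs(medoids[i, "hue"] - pal)
    dh <- pmin(dh, 1 - dh)            # hue circle distance
    dh[used] <- Inf
    g <- which.min(dh)
    map[i] <- g
    used[g] <- TRUE
  }
  map
}

#' Run the digitization simulation study
#'
#' For every plot in the scenario grid: simulate a cohort, estimate the
#' true Kaplan-Meier step functions per group, render the plot as JPEG,
#' digitize the image back with the matching per-plot configuration, and
#' score each curve by checkpoint RMSE against its truth. Digitization
#' failures are recorded per plot, not fatal.
#'
#' @param grid scenario data.frame as from [scenarioGrid()] (default: the
#'   full 60-plot grid).
#' @param seed master seed; each plot derives its own sub-seed from it.
#' @param dir directory for the rendered images (default `tempdir()`).
#' @param n_checkpoints RMSE checkpoints per curve (default 100).
#' @param keep_images keep the rendered JPEGs (default FALSE).
#' @param quiet suppress per-plot progress messages (default TRUE).
#' @return list with `plots` (plot-level table: `plot_id`, `n`,
#'   `n_curves`, `censoring`, `style`, `rmse`, `status`), `curves`
#'   (curve-level RMSE with scenario covariates) and `digitized` (list of
#'   per-plot digitized curve tables).
#' @export
runSimulationStudy <- function(grid = scenarioGrid(), seed = 1,
                               dir = tempdir(), n_checkpoints = 100,
                               keep_images = FALSE, quiet = TRUE) {
  plots <- grid
  plots$rmse <- NA_real_
  plots$status <- "ok"
  curveRows <- list()
  digitized <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    gi <- grid[i, ]
    plotSeed <- (as.integer(seed) %% 1000000L) * 1000L + gi$plot_id
    cohort <- simulateCohort(gi$n, n_groups = gi$n_curves,
                             censoring = gi$censoring, seed = plotSeed)
    truths <- lapply(seq_len(gi$n_curves), function(g) kmEstimate(cohort, g))
    censT <- lapply(seq_len(gi$n_curves), function(g) {
      cohort$time[cohort$group == g & cohort$status == 0L]
    })
    img <- file.path(dir, sprintf("km_plot_%03d.jpeg", gi$plot_id))
    meta <- renderKMPlot(truths, style = gi$style,
                         censor_marks = gi$censoring, censor_times = censT,
                         path = img)
    cfg <- pipelineConfig(
      image_path = img, n_curves = gi$n_curves,
      x_start = meta$x_axis[1], x_end = meta$x_axis[2],
      x_increment = meta$x_axis[3],
      y_start = meta$y_axis[1], y_end = meta$y_axis[2],
      y_increment = meta$y_axis[3],
      ocr_enabled = FALSE, seed = plotSeed
    )
    res <- tryCatch(runPipeline(cfg), error = function(e) e)
    if (inherits(res, "error")) {
      plots$status[i] <- paste0("failed: ", conditionMessage(res))
      if (!keep_images) unlink(img)
      next
    }
    digitized[[i]] <- res$curves
    groupOf <- .matchCurvesToGroups(res$report$medoids, gi$n_curves)
    rmses <- vapply(seq_len(gi$n_curves), function(k) {
      tab <- res$curves[res$curves$curve == k, , drop = FALSE]
      dg <- stepFunction(tab$time, tab$St)
      rmseCurve(dg, truths[[groupOf[k]]], n_checkpoints = n_checkpoints)
    }, numeric(1))
    plots$rmse[i] <- mean(rmses)
    curveRows[[i]] <- data.frame(
      plot_id = gi$plot_id, curve = seq_len(gi$n_curves),
      group = groupOf, n = gi$n, n_curves = gi$n_curves,
      censoring = gi$censoring, style = gi$style, rmse = rmses
    )
    if (!keep_images) unlink(img)
    if (!quiet) {
      message(sprintf("plot %d/%d (n=%d, %d curve(s), censoring=%s, %s): RMSE %.4f",
                      i, nrow(grid), gi$n, gi$n_curves, gi$censoring,
                      gi$style, plots$rmse[i]))
    }
  }
  list(plots = plots, curves = do.call(rbind, curveRows),
       digitized = digitized)
}

#' Score a digitized curve table against a truth table
#'
#' Both tables are long-format (`time`, `St`, `curve`); curves are paired
#' by their `curve` value and each pair is scored with [rmseCurve()].
#'
#' @param digitized,truth long-format curve tables.
#' @param n_checkpoints checkpoints per curve (default 100).
#' @return data.frame with `curve` and `rmse`.
#' @export
evaluateDigitization <- function(digitized, truth, n_checkpoints = 100) {
  ids <- sort(unique(truth$curve))
  out <- lapply(ids, function(k) {
    tt <- truth[truth$curve == k, , drop = FALSE]
    dd <- digitized[digitized$curve == k, , drop = FALSE]
    if (nrow(dd) == 0L) {
      kmStop("kmInputError", "digitized table lacks curve %s", k)
    }
    data.frame(curve = k, rmse = rmseCurve(
      stepFunction(dd$time, dd$St), stepFunction(tt$time, tt$St),
      n_checkpoints = n_checkpoints
    ))
  })
  do.call(rbind, out)
}
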