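# a grid with an axis frame and tick marks at known pixel positions
makeTickFixture <- function() {
  L <- matrix(1, 700, 900)
  L[, 60] <- 0            # y axis line
  L[650, ] <- 0           # x axis line
  # y ticks (rows 100 and 600, i.e. values 1.0 and 0.0), left of the axis
  L[100, 50:58] <- 0
  L[600, 50:58] <- 0
  # x ticks every 120 px from col 70, below the axis
  for (cc in seq(70, 850, by = 120)) L[652:659, cc] <- 0
  makeGrid(L)
}

test_that("calibrateAxes derives units-per-pixel from tick geometry", {
  g <- makeTickFixture()
  ax <- detectAxes(g)
  # only the extreme y ticks are drawn: two-point map onto (0, 1)
  expect_warning(
    cal <- calibrateAxes(g, ax, x_start = 0, x_end = 36, x_increment = 6,
                         y_start = 0, y_end = 1, y_increment = 0.25),
    class = "kmTickCountWarning"
  )
  expect_equal(cal@yUnitsPerPx, 1 / 500)        # rows 100..600
  expect_equal(cal@yOriginPx, 600)
  # x ticks every 120 px, increment 6 time units: 0.05 units per px
  expect_equal(cal@xUnitsPerPx, 0.05)
  expect_equal(cal@xOriginPx, 70)
  expect_error(
    calibrateAxes(g, ax, 0, 36, 0, 0, 1, 0.25),
    class = "kmInputError"
  )
})

test_that("calibrateAxes falls back to the region extent without ticks", {
  g <- makeAxesFixture()  # axes but no ticks at all
  ax <- detectAxes(g)
  # both axes fall back: one warning per axis
  expect_warning(
    expect_warning(
      cal <- calibrateAxes(g, ax, 0, 100, 25, 0, 1, 0.25),
      class = "kmTickFallbackWarning"
    ),
    class = "kmTickFallbackWarning"
  )
  r <- ax@plotRegion
  expect_equal(cal@xUnitsPerPx, 100 / (r["colMax"] - r["colMin"]),
               ignore_attr = TRUE)
})

test_that("mapToUnits maps, collapses and compresses a traced path", {
  cal <- new("AxisCalibration",
             xOriginPx = 10, xUnitsPerPx = 0.5,
             yOriginPx = 210, yUnitsPerPx = 0.005,
             declaredX = c(0, 100, 10), declaredY = c(0, 1, 0.25))
  axes <- new("AxesGeometry", yAxisCol = 5L, xAxisRow = 215L,
              plotRegion = c(colMin = 8L, colMax = 320L,
                             rowMin = 1L, rowMax = 212L))
  # origin pixel maps to (0, 1)
  p0 <- new("TracedPath", curveId = 1L,
            steps = cbind(10:12, c(10L, 10L, 10L)))
  dc0 <- mapToUnits(p0, cal, axes)
  expect_equal(curvePoints(dc0)$time[1], 0)
  expect_equal(curvePoints(dc0)$St[1], 1)

  # flat path across 300 columns compresses to exactly 2 points
  pFlat <- new("TracedPath", curveId = 1L,
               steps = cbind(10:309, rep(50L, 300)))
  dcFlat <- mapToUnits(pFlat, cal, axes)
  expect_equal(nrow(curvePoints(dcFlat)), 2L)

  # a staircase: vertical drop collapses to the bottom-most row per column
  steps <- rbind(cbind(10:14, 10L), cbind(14L, 11:20), cbind(15:19, 20L))
  pSt <- new("TracedPath", curveId = 1L, steps = steps)
  pts <- curvePoints(mapToUnits(pSt, cal, axes))
  expect_true(all(diff(pts$time) > 0))
  expect_true(all(diff(pts$St) <= 0))
  # at the drop column only the post-drop level remains (right-continuity)
  expect_equal(pts$St[pts$time == (14 - 10) * 0.5], (210 - 20) * 0.005)

  # survival far outside [0, 1] signals a calibration problem
  pBad <- new("TracedPath", curveId = 1L,
              steps = cbind(10:12, c(150L, 150L, 150L)))
  calBad <- new("AxisCalibration",
                xOriginPx = 10, xUnitsPerPx = 0.5,
                yOriginPx = 210, yUnitsPerPx = 0.05,
                declaredX = c(0, 100, 10), declaredY = c(0, 1, 0.25))
  expect_error(mapToUnits(pBad, calBad, axes), class = "kmCalibrationError")
})

test_that("a rendered one-step function digitizes to the known geometry", {
  # S = 1 on [0, 10), 0.6 on [10, 20]
  f <- stepFunction(c(0, 10, 20), c(1, 0.6, 0.6))
  img <- tempfile(fileext = ".jpeg")
  meta <- renderKMPlot(list(f), style = "style_a", path = img,
                       x_axis = c(0, 20, 5))
  cfg <- pipelineConfig(image_path = img, n_curves = 1,
                        x_start = 0, x_end = 20, x_increment = 5,
                        y_start = 0, y_end = 1, y_increment = 0.25)
  res <- runPipeline(cfg)
  tab <- res$curves
  pxW <- 20 / (meta$geometry$region_width - 1)   # time units per pixel
  pxH <- 1 / (meta$geometry$region_height - 1)   # survival units per pixel
  # the step (midpoint crossing) lands within one pixel-width of t = 10
  stepAt <- min(tab$time[tab$St <= 0.8 + 1e-9])
  expect_lte(abs(stepAt - 10), pxW + 1e-9)
  # levels recovered within two pixel-heights away from the step
  lev1 <- tab$St[tab$time < 10 - 2 * pxW]
  lev2 <- tab$St[tab$time > 10 + 2 * pxW]
  expect_lte(max(abs(lev1 - 1)), 2 * pxH + 1e-9)
  expect_lte(max(abs(lev2 - 0.6)), 2 * pxH + 1e-9)
  unlink(img)
})

test_that("aggregateCurves builds the long table", {
  a <- new("DigitizedCurve", curveId = 1L,
           points = data.frame(time = c(0, 5, 9), St = c(1, 0.8, 0.4)))
  b <- new("DigitizedCurve", curveId = 2L,
           points = data.frame(time = c(0, 4), St = c(1, 0.5)))
  t1 <- aggregateCurves(list(a))
  expect_equal(names(t1), c("id", "time", "St", "curve"))
  expect_equal(t1$id, 1:3)
  t2 <- aggregateCurves(list(a, b))
  expect_setequal(unique(t2$curve), c(1L, 2L))
  expect_equal(t2$id[t2$curve == 2], 1:2)
  expect_error(aggregateCurves(list()), class = "kmInputError")
})
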