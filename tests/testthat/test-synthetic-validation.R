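test_that("simulateCohort draws competing exponentials with the study rates", {
  co <- simulateCohort(10, censoring = FALSE, seed = 1)
  expect_true(all(co$status == 1L))
  expect_true(all(co$time > 0))

  big <- simulateCohort(1e5, censoring = TRUE, seed = 2)
  # P(event before censoring) = 0.01 / (0.01 + 0.005) = 2/3
  expect_equal(mean(big$status), 2 / 3, tolerance = 0.015)
  # min of the two exponentials is Exp(0.015): mean 66.7
  expect_equal(mean(big$time), 1 / 0.015, tolerance = 0.02)

  co3 <- simulateCohort(30, n_groups = 3, seed = 3)
  expect_setequal(unique(co3$group), 1:3)
  # same seed reproduces the cohort exactly
  expect_identical(co3, simulateCohort(30, n_groups = 3, seed = 3))
})

test_that("kmEstimate matches hand-computed product limits", {
  # two events
  f <- kmEstimate(data.frame(time = c(1, 2), status = c(1, 1)))
  expect_equal(stepTimes(f), c(0, 1, 2))
  expect_equal(stepSurv(f), c(1, 0.5, 0))
  # event then censoring: no second drop
  f2 <- kmEstimate(data.frame(time = c(1, 2), status = c(1, 0)))
  expect_equal(stepSurv(f2), c(1, 0.5, 0.5))
  expect_equal(max(stepTimes(f2)), 2)   # last knot is the max study time
})

test_that("kmEstimate equals the risk-set recount oracle on random cohorts", {
  set.seed(11)
  for (r in 1:40) {
    n <- sample(3:40, 1)
    co <- simulateCohort(n, censoring = TRUE, seed = 1000 + r)
    f <- kmEstimate(co)
    o <- bruteKM(co$time, co$status)
    expect_equal(stepTimes(f), o$time)
    expect_equal(stepSurv(f), o$surv)
  }
})

test_that("remapProbability applies the exhaustion rule", {
  f <- stepFunction(c(0, 1, 2), c(1, 0.8, 0.5))
  expect_equal(remapProbability(f, 1.5), 0.8)   # last knot at or below t
  expect_equal(remapProbability(f, 2.5), 0)     # all knots <= t: exhausted
  expect_equal(remapProbability(f, 2), 0)       # boundary: all knots <= t
  expect_equal(remapProbability(f, 0), 1)       # knot at 0
  expect_equal(remapProbability(f, c(0.5, 1, 1.99)), c(1, 0.8, 0.8))
  # piecewise-constant and non-increasing up to the last knot
  tt <- seq(0, 1.999, by = 0.001)
  v <- remapProbability(f, tt)
  expect_true(all(diff(v) <= 0))
  expect_setequal(unique(v), c(1, 0.8))
})

test_that("rmseCurve reproduces hand-summed checkpoint errors", {
  f <- stepFunction(c(0, 5, 10), c(1, 0.6, 0.2))
  expect_equal(rmseCurve(f, f), 0)
  # constant offset at every checkpoint except the final one, where the
  # exhaustion rule sends both curves to 0: rmse = 0.02 * sqrt(99/100)
  g <- stepFunction(c(0, 5, 10), c(1, 0.6, 0.2) - 0.02)
  expect_equal(rmseCurve(g, f), 0.02 * sqrt(99 / 100))
  # 3-knot toy at 5 checkpoints: explicit arithmetic oracle
  a <- stepFunction(c(0, 4, 8), c(1, 0.7, 0.3))
  b <- stepFunction(c(0, 2, 8), c(1, 0.9, 0.4))
  cp <- seq(0, 8, length.out = 5)            # 0, 2, 4, 6, 8
  av <- c(1, 1, 0.7, 0.7, 0)                  # a at cp (8 exhausts a)
  bv <- c(1, 0.9, 0.9, 0.9, 0)                # b at cp
  expect_equal(rmseCurve(a, b, n_checkpoints = 5),
               sqrt(mean((av - bv)^2)))
  # symmetric when the curves share their last knot
  expect_equal(rmseCurve(a, b, 5), rmseCurve(b, a, 5))
  expect_error(rmseCurve(a, b, 1), class = "kmInputError")
})

test_that("blandAltman computes mean difference and 1.96 SD limits", {
  a <- c(0.9, 0.8, 0.7)
  expect_equal(unname(blandAltman(a, a)), c(0, 0, 0))
  expect_equal(unname(blandAltman(a + 0.01, a)), c(0.01, 0.01, 0.01))
  ba <- blandAltman(c(0.99, 0.81), c(1, 0.8))  # d = -0.01, +0.01
  s <- sd(c(-0.01, 0.01))
  expect_equal(unname(ba), c(0, -1.96 * s, 1.96 * s))
  expect_error(blandAltman(1:3, 1:2), class = "kmInputError")
})

test_that("kendallTau is tie-corrected and flags degenerate series", {
  ref <- stepFunction(c(0, 2, 4, 6, 8), c(1, 0.8, 0.6, 0.4, 0.2))
  expect_equal(kendallTau(ref, ref), 1.0)
  # a tied candidate: compare against brute-force pair counting
  cand <- stepFunction(c(0, 2, 4), c(1, 0.6, 0.6))
  b <- remapProbability(cand, stepTimes(ref))
  expect_equal(kendallTau(ref, cand), bruteTauB(stepSurv(ref), b))
  # constant candidate series: undefined
  flat <- stepFunction(c(0, 10), c(0.5, 0.5))
  expect_warning(v <- kendallTau(ref, flat),
                 class = "kmDegenerateSeriesWarning")
  expect_true(is.na(v))
})

test_that("stats and brute-force tau-b agree on random tied series", {
  set.seed(5)
  for (r in 1:20) {
    x <- sample(1:6, 8, TRUE); y <- sample(1:6, 8, TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(cor(x, y, method = "kendall"), bruteTauB(x, y))
  }
})

test_that("the scenario grid crosses to 60 plots and 120 curves", {
  g <- scenarioGrid()
  expect_equal(nrow(g), 60L)
  expect_equal(sum(g$n_curves), 120L)
  expect_setequal(unique(g$n), c(25L, 50L, 150L, 250L, 1000L))
  expect_setequal(unique(g$style), c("style_a", "style_b"))
  expect_equal(sum(g$censoring), 30L)
  expect_equal(g$plot_id, 1:60)
})

test_that("renderKMPlot writes decodable JPEGs with the documented styles", {
  f <- stepFunction(c(0, 50, 100), c(1, 0.5, 0.2))
  imgA <- tempfile(fileext = ".jpeg"); imgB <- tempfile(fileext = ".jpeg")
  renderKMPlot(list(f), style = "style_a", path = imgA)
  metaB <- renderKMPlot(list(f), style = "style_b", path = imgB)
  gB <- loadImage(imgB)
  # the gray panel of style_b counts as background (lightness >= 0.8)
  geo <- metaB$geometry
  panel <- gB@lightness[geo$data_row0 + 300:320, geo$data_col0 + 1200:1250]
  expect_true(mean(panel >= 0.8) > 0.95)
  # palette hues pairwise separated by at least 60 degrees on the circle
  pal <- kmdigitize:::.kmPalette()$hue
  for (i in 1:2) for (j in (i + 1):3) {
    d <- abs(pal[i] - pal[j]); d <- min(d, 1 - d)
    expect_gte(d, 1 / 6)
  }
  # censor ticks appear at the requested times in the curve's colour
  imgC <- tempfile(fileext = ".jpeg")
  metaC <- renderKMPlot(list(f), style = "style_a", censor_marks = TRUE,
                        censor_times = list(c(25)), path = imgC,
                        x_axis = c(0, 100, 25))
  gC <- loadImage(imgC)
  cc <- metaC$geometry$data_col0 + round(25 / 100 * 1599)
  rr <- metaC$geometry$data_row0 + 0:4   # S = 1 at t = 25: top rows
  expect_true(any(gC@saturation[rr, cc + 0:1] > 0.3))
  unlink(c(imgA, imgB, imgC))
})

test_that("a restricted clean scenario digitizes below 0.01 RMSE", {
  g <- scenarioGrid()
  g1 <- g[g$n == 150 & g$n_curves == 1 & !g$censoring & g$style == "style_a", ]
  res <- runSimulationStudy(grid = g1, seed = 4)
  expect_equal(nrow(res$plots), 1L)
  expect_equal(res$plots$status, "ok")
  expect_lt(res$plots$rmse, 0.01)
  # determinism: an identical run reproduces the table byte for byte
  res2 <- runSimulationStudy(grid = g1, seed = 4)
  expect_identical(res$plots, res2$plots)
  expect_identical(res$digitized, res2$digitized)
})

test_that("evaluateDigitization scores curve tables pairwise", {
  tt <- data.frame(time = c(0, 10, 20), St = c(1, 0.6, 0.3), curve = 1)
  dd <- data.frame(time = c(0, 10, 20), St = c(1, 0.6, 0.3) - 0.01, curve = 1)
  out <- evaluateDigitization(dd, tt)
  expect_equal(out$rmse, 0.01 * sqrt(99 / 100), tolerance = 1e-9)
  expect_error(evaluateDigitization(dd[0, ], tt), class = "kmInputError")
})
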