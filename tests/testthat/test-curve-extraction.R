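test_that("clusterPixels splits colour blobs like exhaustive k-medoids", {
  set.seed(42)
  # two colour blobs, 28 pixels total (small enough for brute force)
  red <- data.frame(col = sample(1:30, 14, TRUE), row = sample(1:30, 14, TRUE),
                    hue = runif(14, 0.00, 0.03), saturation = 0.8,
                    lightness = runif(14, 0.40, 0.50))
  blu <- data.frame(col = sample(1:30, 14, TRUE), row = sample(1:30, 14, TRUE),
                    hue = runif(14, 0.63, 0.70), saturation = 0.8,
                    lightness = runif(14, 0.40, 0.50))
  px <- rbind(red, blu)
  mask <- new("CurvePixelMask", pixels = px,
              region = c(colMin = 1L, colMax = 32L, rowMin = 1L, rowMax = 32L))
  cs <- clusterPixels(mask, 2)
  lab <- maskPixels(cs)$label
  expect_equal(length(unique(lab[1:14])), 1L)
  expect_equal(length(unique(lab[15:28])), 1L)
  expect_true(lab[1] != lab[15])

  # brute force: try every medoid pair, minimize total distance
  feat <- cbind(px$hue * 2, px$saturation, px$lightness)
  n <- nrow(feat)
  bestCost <- Inf; bestLab <- NULL
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d1 <- sqrt(colSums((t(feat) - feat[i, ])^2))
    d2 <- sqrt(colSums((t(feat) - feat[j, ])^2))
    cost <- sum(pmin(d1, d2))
    if (cost < bestCost) { bestCost <- cost; bestLab <- ifelse(d1 <= d2, 1L, 2L) }
  }
  # same partition up to label swap
  agree <- mean(bestLab == lab)
  expect_true(agree == 1 || agree == 0)
})

test_that("clusterPixels handles k = 1, drop_dark and hue wraparound", {
  px <- data.frame(col = 1:20, row = 1, hue = 0.5, saturation = 1,
                   lightness = c(rep(0.5, 15), rep(0.1, 5)))
  mask <- new("CurvePixelMask", pixels = px,
              region = c(colMin = 1L, colMax = 22L, rowMin = 1L, rowMax = 3L))
  cs1 <- clusterPixels(mask, 1)
  expect_equal(maskPixels(cs1)$label, rep(1L, 20))

  # near-black censoring pixels dropped before clustering
  cs2 <- clusterPixels(mask, 1, drop_dark = TRUE)
  expect_true(all(maskPixels(cs2)$lightness > 0.2))
  expect_equal(nrow(maskPixels(cs2)), 15L)

  # a red cloud straddling the hue wrap point must stay one cluster
  set.seed(1)
  px3 <- data.frame(
    col = 1:40, row = 1,
    hue = c(runif(10, 0.97, 0.999), runif(10, 0, 0.03),   # red, wrapped
            runif(20, 0.60, 0.70)),                        # blue
    saturation = 0.8, lightness = 0.45
  )
  mask3 <- new("CurvePixelMask", pixels = px3,
               region = c(colMin = 1L, colMax = 42L, rowMin = 1L, rowMax = 3L))
  lab3 <- maskPixels(clusterPixels(mask3, 2))$label
  expect_equal(length(unique(lab3[1:20])), 1L)
  expect_equal(length(unique(lab3[21:40])), 1L)
  expect_true(lab3[1] != lab3[21])

  expect_error(clusterPixels(mask, 25), class = "kmClusterError")
})

test_that("knnScore reproduces the direct substitution examples", {
  # single same-cluster neighbour at distance 1
  px <- data.frame(col = c(5, 5), row = c(5, 6), label = c(1L, 1L))
  expect_equal(knnScore(5, 5, px, k = 1), 1.0)
  # same-cluster at d=1 plus other-cluster at d=2: 1/1 - 1/4
  px <- data.frame(col = c(5, 5, 5), row = c(5, 6, 7), label = c(1L, 1L, 2L))
  expect_equal(knnScore(5, 5, px, k = 2), 0.75)
  # three other-cluster neighbours all at distance 1
  px <- data.frame(col = c(5, 4, 6, 5), row = c(5, 5, 5, 6),
                   label = c(1L, 2L, 2L, 2L))
  expect_equal(knnScore(5, 5, px, k = 3), -3.0)
  # fewer than k neighbours: uses all available with a warning
  px <- data.frame(col = c(5, 6), row = c(5, 5), label = c(1L, 1L))
  expect_warning(s <- knnScore(5, 5, px, k = 10),
                 class = "kmSmallSetWarning")
  expect_equal(s, 1.0)
})

test_that("knnScore agrees with the brute-force oracle on random sets", {
  set.seed(7)
  for (rep in 1:25) {
    n <- 50
    px <- data.frame(col = sample(1:40, n, TRUE), row = sample(1:40, n, TRUE),
                     label = sample(1:3, n, TRUE))
    px <- px[!duplicated(px[, c("col", "row")]), ]
    i <- sample(nrow(px), 1)
    k <- sample(c(1, 5, 20), 1)
    expect_equal(
      knnScore(px$col[i], px$row[i], px, k = k),
      bruteKnnScore(px$col[i], px$row[i], px, k = k, label = px$label[i])
    )
  }
})

test_that("tracePath follows a clean staircase exactly", {
  px <- makeStaircase()
  cs <- makeClusterSet(px)
  p <- tracePath(cs, 1)
  steps <- pathSteps(p)
  expect_equal(nrow(steps), nrow(px))
  expect_setequal(paste(steps[, 1], steps[, 2]), paste(px$col, px$row))
  # staircase property enforced by the class validity
  expect_true(validObject(p))
})

test_that("tracePath reduces a thick staircase to a monotone single-pixel path", {
  base <- makeStaircase(runs = c(8L, 7L, 9L), drops = c(4L, 3L))
  thick <- do.call(rbind, lapply(-1:1, function(d) {
    transform(base, row = row + d)
  }))
  thick <- thick[!duplicated(thick[, c("col", "row")]), ]
  thick$row <- thick$row + 2L  # keep rows positive
  cs <- makeClusterSet(thick)
  p <- tracePath(cs, 1)
  steps <- pathSteps(p)
  # every step lies inside the thick line
  expect_true(all(paste(steps[, 1], steps[, 2]) %in%
                  paste(thick$col, thick$row)))
  # row never decreases; at most one pixel per column after collapse
  expect_true(all(diff(steps[, 2]) >= 0))
  collapsed <- steps[!duplicated(steps[, 1], fromLast = TRUE), , drop = FALSE]
  expect_equal(anyDuplicated(collapsed[, 1]), 0L)
  # bounded length
  r <- plotRegion(cs)
  expect_lte(nrow(steps),
             (r["colMax"] - r["colMin"] + 2) + (r["rowMax"] - r["rowMin"] + 2))
})

test_that("tracePath bridges a hole and rejoins at the pre-gap row", {
  px <- data.frame(col = c(3:12, 18:27), row = 5L, label = 1L)  # 5-col hole
  cs <- makeClusterSet(px)
  p <- tracePath(cs, 1)
  steps <- pathSteps(p)
  expect_equal(steps[, 2], rep(5L, nrow(steps)))     # stays on the row
  expect_equal(range(steps[, 1]), c(3L, 27L))        # continues to the end
  expect_equal(nrow(steps), 25L)                     # hole filled in
})

test_that("two separated curves trace without cross-assignment", {
  c1 <- makeStaircase(startCol = 3L, startRow = 4L,
                      runs = c(6L, 6L, 6L), drops = c(3L, 3L))
  c2 <- makeStaircase(startCol = 3L, startRow = 30L,
                      runs = c(5L, 7L, 6L), drops = c(4L, 2L))
  c2$label <- 2L
  cs <- makeClusterSet(rbind(c1, c2))
  p1 <- pathSteps(tracePath(cs, 1))
  p2 <- pathSteps(tracePath(cs, 2))
  expect_true(all(paste(p1[, 1], p1[, 2]) %in% paste(c1$col, c1$row)))
  expect_true(all(paste(p2[, 1], p2[, 2]) %in% paste(c2$col, c2$row)))
})
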