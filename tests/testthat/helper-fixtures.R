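# Fixture builders and independent oracles shared across the suite.
# Everything is generated in code; no binary fixtures are stored.

# PixelGrid from a lightness matrix (hue/saturation default to 0)
makeGrid <- function(L, H = NULL, S = NULL) {
  if (is.null(H)) H <- matrix(0, nrow(L), ncol(L))
  if (is.null(S)) S <- matrix(0, nrow(L), ncol(L))
  new("PixelGrid", width = ncol(L), height = nrow(L),
      hue = H, saturation = S, lightness = L)
}

# white 300x400 image with a black vertical axis at col 40 and a black
# horizontal axis at row 260
makeAxesFixture <- function(extraCol = NULL) {
  L <- matrix(1, 300, 400)
  L[, 40] <- 0
  L[260, ] <- 0
  if (!is.null(extraCol)) L[, extraCol] <- 0
  makeGrid(L)
}

# CurveClusterSet built directly from a pixel data frame (col, row, label)
makeClusterSet <- function(px, region = NULL, medoids = NULL) {
  if (is.null(region)) {
    region <- c(colMin = 1L, colMax = max(px$col) + 2L,
                rowMin = 1L, rowMax = max(px$row) + 2L)
  }
  k <- max(px$label)
  if (is.null(medoids)) {
    medoids <- matrix(rep(c(0, 1, 0.5), each = k), k, 3,
                      dimnames = list(NULL, c("hue", "saturation", "lightness")))
  }
  px$hue <- if ("hue" %in% names(px)) px$hue else 0
  px$saturation <- if ("saturation" %in% names(px)) px$saturation else 1
  px$lightness <- if ("lightness" %in% names(px)) px$lightness else 0.5
  new("CurveClusterSet", pixels = px, medoids = medoids,
      region = as.integer(region) |> stats::setNames(c("colMin", "colMax", "rowMin", "rowMax")))
}

# a monotone staircase pixel set: right runs and drops, single pixel wide
makeStaircase <- function(startCol = 3L, startRow = 4L,
                          runs = c(5L, 4L, 6L), drops = c(3L, 2L)) {
  cols <- integer(0); rows <- integer(0)
  cc <- startCol; rr <- startRow
  for (i in seq_along(runs)) {
    cols <- c(cols, cc:(cc + runs[i] - 1L)); rows <- c(rows, rep(rr, runs[i]))
    cc <- cc + runs[i] - 1L
    if (i <= length(drops)) {
      rows <- c(rows, (rr + 1L):(rr + drops[i])); cols <- c(cols, rep(cc, drops[i]))
      rr <- rr + drops[i]
    }
    cc <- cc + 1L
  }
  data.frame(col = cols, row = rows, label = 1L)
}

# O(n^2) brute-force knn score: full sort with the package's tie-break
# ((distance, col, row) lexicographic), +1/-1 votes weighted by 1/d^2
bruteKnnScore <- function(col, row, px, k, label) {
  other <- px[!(px$col == col & px$row == row), , drop = FALSE]
  d2 <- (other$col - col)^2 + (other$row - row)^2
  ord <- order(d2, other$col, other$row)
  kk <- min(k, nrow(other))
  sel <- ord[seq_len(kk)]
  sum(ifelse(other$label[sel] == label, 1, -1) / d2[sel])
}

# independent product-limit oracle: explicit risk-set recount at every
# distinct observed time
bruteKM <- function(time, status) {
  ts <- sort(unique(time))
  S <- 1
  surv <- numeric(length(ts))
  for (i in seq_along(ts)) {
    atRisk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & status == 1)
    if (atRisk > 0) S <- S * (1 - d / atRisk)
    surv[i] <- S
  }
  list(time = c(0, ts), surv = c(1, surv))
}

# brute-force Kendall tau-b by pair enumeration with tie corrections
bruteTauB <- function(x, y) {
  n <- length(x)
  C <- D <- tx <- ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    a <- sign(x[j] - x[i]); b <- sign(y[j] - y[i])
    if (a * b > 0) C <- C + 1 else if (a * b < 0) D <- D + 1
    if (a == 0 && b != 0) tx <- tx + 1
    if (b == 0 && a != 0) ty <- ty + 1
    if (a == 0 && b == 0) { tx <- tx + 1; ty <- ty + 1 }
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - tx) * (n0 - ty))
}

# render one cohort's plot and digitize it back; returns truths, the
# digitized tables and the curve -> group matching
digitizeCohort <- function(cohort, n_curves, style = "style_a",
                           censor_marks = FALSE, seed = 5,
                           region_width = 1600L, region_height = 1000L) {
  truths <- lapply(seq_len(n_curves), function(g) kmEstimate(cohort, g))
  censT <- lapply(seq_len(n_curves), function(g) {
    cohort$time[cohort$group == g & cohort$status == 0]
  })
  img <- tempfile(fileext = ".jpeg")
  on.exit(unlink(img))
  meta <- renderKMPlot(truths, style = style, censor_marks = censor_marks,
                       censor_times = censT, path = img,
                       region_width = region_width,
                       region_height = region_height)
  cfg <- pipelineConfig(
    image_path = img, n_curves = n_curves,
    x_start = meta$x_axis[1], x_end = meta$x_axis[2],
    x_increment = meta$x_axis[3],
    y_start = meta$y_axis[1], y_end = meta$y_axis[2],
    y_increment = meta$y_axis[3], seed = seed
  )
  res <- runPipeline(cfg)
  list(truths = truths, curves = res$curves, report = res$report,
       groupOf = kmdigitize:::.matchCurvesToGroups(res$report$medoids, n_curves),
       meta = meta)
}
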