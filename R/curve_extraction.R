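## Colour clustering and monotone path tracing.
##
## Curves are separated in HSL feature space by k-medoids (PAM); each
## curve is then reduced to a single-pixel-wide monotone staircase. Where
## the trace must choose between stepping right and stepping down, a
## signed, inverse-square-distance-weighted k-nearest-neighbour vote
## decides: a pixel deep inside its own curve's band outscores an artifact
## or a stray censoring-mark pixel, so the path sticks to the coherent
## route and rides over overlaps.

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Cluster curve pixels by colour with k-medoids
#'
#' Each pixel is embedded as `(hue * hue_boost, saturation,
#' lightness * light_boost)` and partitioned by PAM k-medoids with
#' k = `n_curves`. Boosting the hue keeps colour the dominant separator.
#' For masks larger than `pam_max` pixels the medoids are found by
#' `cluster::clara` (PAM on repeated subsamples) since full PAM scales
#' quadratically; below that, exact `cluster::pam` is used. With
#' `drop_dark = TRUE`, pixels at or below lightness `dark_threshold`
#' (black censoring marks or lines) are discarded before clustering.
#'
#' Hue is circular: a saturated red sits at both ends of [0, 1), and
#' compression noise spreads its pixels across the wrap point. Before
#' clustering, the hue axis is therefore cut at the centre of the largest
#' empty arc of the observed hue distribution and shifted, so no curve's
#' pixels straddle the seam; reported medoids are mapped back to the
#' original hue scale.
#'
#' Cluster labels are relabelled deterministically by ascending medoid
#' (hue, lightness, saturation), so curve 1 is always the lowest-hue curve.
#'
#' @param mask a [CurvePixelMask-class].
#' @param n_curves number of curves in the plot (k).
#' @param hue_boost,light_boost multiplicative channel weights
#'   (defaults 2 and 1).
#' @param drop_dark discard near-black pixels before clustering
#'   (default FALSE).
#' @param seed RNG seed used by the subsampled PAM path (default 42).
#' @param dark_threshold lightness cutoff for `drop_dark` (default 0.2).
#' @param pam_max mask size above which clara replaces exact PAM
#'   (default 3000).
#' @return A [CurveClusterSet-class].
#' @export
clusterPixels <- function(mask, n_curves, hue_boost = 2, light_boost = 1,
                          drop_dark = FALSE, seed = 42,
                          dark_threshold = 0.2, pam_max = 3000L) {
  stopifnot(is(mask, "CurvePixelMask"))
  if (n_curves < 1L) kmStop("kmInputError", "n_curves must be >= 1")
  if (hue_boost <= 0 || light_boost <= 0) {
    kmStop("kmInputError", "channel boosts must be positive")
  }
  px <- mask@pixels
  if (isTRUE(drop_dark)) px <- px[px$lightness > dark_threshold, , drop = FALSE]
  n <- nrow(px)
  if (n < n_curves) {
    kmStop("kmClusterError",
           "only %d pixels remain but %d curves requested", n, n_curves)
  }
  cut <- .hueCutPoint(px$hue)
  hShift <- (px$hue - cut) %% 1
  feat <- cbind(hShift * hue_boost, px$saturation, px$lightness * light_boost)
  if (n_curves == 1L) {
    labels <- rep(1L, n)
    ctr <- colMeans(feat)
    med <- feat[which.min(colSums((t(feat) - ctr)^2)), ]
  } else if (n <= pam_max) {
    fit <- cluster::pam(feat, k = n_curves, keep.diss = FALSE,
                        keep.data = FALSE)
    labels <- as.integer(fit$clustering)
    med <- fit$medoids
  } else {
    fit <- .withSeed(seed, cluster::clara(
      feat, k = n_curves, samples = 5,
      sampsize = min(n, 1000L), pamLike = TRUE
    ))
    labels <- as.integer(fit$clustering)
    med <- fit$medoids
  }
  med <- matrix(med, ncol = 3)
  med <- sweep(med, 2, c(hue_boost, 1, light_boost), "/")
  med[, 1] <- (med[, 1] + cut) %% 1
  colnames(med) <- c("hue", "saturation", "lightness")
  if (!all(seq_len(n_curves) %in% labels)) {
    kmStop("kmClusterError",
           "clustering produced an empty curve; adjust hue_boost/light_boost")
  }
  # deterministic labels: curve 1 = lowest medoid hue
  ord <- order(med[, "hue"], med[, "lightness"], med[, "saturation"])
  relab <- integer(n_curves); relab[ord] <- seq_len(n_curves)
  px$label <- relab[labels]
  med <- med[ord, , drop = FALSE]
  new("CurveClusterSet", pixels = px, medoids = med, region = mask@region)
}

## Cut point for the circular hue axis: the centre of the longest run of
## empty histogram bins (256 bins over the circle). Shifting hues by the
## cut keeps every colour's noise cloud contiguous on the linear axis.
.hueCutPoint <- function(h, bins = 256L) {
  occ <- tabulate(as.integer(floor(h * bins)) %% bins + 1L, bins)
  if (all(occ > 0L)) return(0)
  # longest circular run of empty bins: unroll twice
  e <- c(occ, occ) == 0L
  best <- 0L; bestStart <- 0L; run <- 0L
  for (i in seq_along(e)) {
    if (e[i]) {
      run <- run + 1L
      if (run > best && i - run + 1L <= bins) {
        best <- run; bestStart <- i - run + 1L
      }
    } else {
      run <- 0L
    }
  }
  best <- min(best, bins)
  (((bestStart - 1L) + best / 2) / bins) %% 1
}

## Integer label matrix over the full image extent, 0 = no pixel.
.labelMatrix <- function(pixels, dims) {
  m <- matrix(0L, dims[1], dims[2])
  m[cbind(pixels$row, pixels$col)] <- as.integer(pixels$label)
  m
}

## Core knn score on a label matrix. Neighbours are the k nearest labelled
## pixels by Euclidean distance (ties broken by (col, row) order); each
## votes +1/-1 for label agreement, weighted by 1/d^2.
.knnScoreGrid <- function(labmat, col, row, own, k, warn = TRUE) {
  H <- nrow(labmat); W <- ncol(labmat)
  r0 <- 4L
  repeat {
    rlo <- max(1L, row - r0); rhi <- min(H, row + r0)
    clo <- max(1L, col - r0); chi <- min(W, col + r0)
    sub <- labmat[rlo:rhi, clo:chi, drop = FALSE]
    idx <- which(sub != 0L)
    nr <- nrow(sub)
    rr <- ((idx - 1L) %% nr) + rlo
    cc <- ((idx - 1L) %/% nr) + clo
    keep <- !(rr == row & cc == col)
    rr <- rr[keep]; cc <- cc[keep]
    d2 <- (rr - row)^2 + (cc - col)^2
    fullWindow <- rlo == 1L && rhi == H && clo == 1L && chi == W
    if (length(d2) >= k && (fullWindow || sort(d2, partial = k)[k] <= r0^2)) {
      break
    }
    if (fullWindow) {
      if (length(d2) == 0L) {
        if (warn) kmWarn("kmSmallSetWarning", "pixel has no neighbours")
        return(0)
      }
      if (warn) {
        kmWarn("kmSmallSetWarning",
               "only %d neighbours available for k = %d", length(d2), k)
      }
      k <- length(d2)
      break
    }
    r0 <- r0 * 2L
  }
  ord <- order(d2, cc, rr)[seq_len(k)]
  lab <- labmat[cbind(rr[ord], cc[ord])]
  sum(ifelse(lab == own, 1, -1) / d2[ord])
}

#' Distance-weighted k-nearest-neighbour cluster-coherence score
#'
#' For a pixel p with cluster label g, the score is
#' \deqn{\sum_{i=1}^{k} comp(p, n_i) / dist(p, n_i)^2}
#' over its k nearest labelled pixels by Euclidean distance, where
#' `comp` is +1 when the neighbour shares p's label and -1 otherwise.
#' Neighbours are taken in ascending distance, distance ties broken by
#' (col, row) lexicographic order. When fewer than k other pixels exist,
#' all available ones are used and a warning is logged.
#'
#' @param col,row pixel coordinates of p.
#' @param pixels data.frame with columns `col`, `row`, `label` (e.g. from
#'   [maskPixels()] of a [CurveClusterSet-class]).
#' @param k number of neighbours (default 20).
#' @param label p's own cluster label; defaults to the label of the
#'   matching pixel in `pixels`.
#' @return The numeric score.
#' @examples
#' px <- data.frame(col = c(1, 1, 3), row = c(1, 2, 1), label = c(1, 1, 2))
#' knnScore(1, 1, px, k = 1)   # same-cluster neighbour at distance 1: 1
#' @export
knnScore <- function(col, row, pixels, k = 20, label = NULL) {
  if (k < 1) kmStop("kmInputError", "k must be >= 1")
  if (is.null(label)) {
    hit <- which(pixels$col == col & pixels$row == row)
    if (length(hit) == 0L) {
      kmStop("kmInputError",
             "pixel (%d, %d) is not in the labelled set; pass label=", col, row)
    }
    label <- pixels$label[hit[1]]
  }
  dims <- c(max(pixels$row, row), max(pixels$col, col))
  labmat <- .labelMatrix(pixels, dims)
  .knnScoreGrid(labmat, as.integer(col), as.integer(row),
                as.integer(label), as.integer(k))
}

#' Trace one curve as a single-pixel-wide monotone staircase
#'
#' Starting from the curve's top-most (then left-most) pixel, the trace
#' repeatedly steps one pixel right or one pixel down. When both forward
#' neighbours belong to the curve, the one with the higher
#' [knnScore()] wins (ties step right); when neither does, the gap is
#' bridged: the trace scans rightward along its current row, up to a
#' horizon of `gap_horizon_frac` of the region width, for the nearest
#' column holding a curve pixel at the same or lower height, fills the
#' gap horizontally (then drops to that pixel); failing that it scans
#' downward within the same column, and otherwise terminates. This fills
#' in segments lost to curve overlaps and ignores detached artifacts.
#'
#' A reconnection target must itself be coherent: candidate pixels with a
#' non-positive knn score (typically colour-blend artifacts sitting on
#' another curve's line) are skipped during the scan. Because two
#' overlapping curves can hide one another for long stretches -- two
#' Kaplan-Meier curves at the same quantized level coincide exactly, and
#' the covering curve owns the shared pixels -- the scan horizon defaults
#' to the full region extent.
#'
#' @param clusters a [CurveClusterSet-class] (all curves: neighbours from
#'   every cluster feed the knn score).
#' @param curve_id which curve to trace.
#' @param knn_k neighbour count for the score (default 20).
#' @param gap_horizon_frac gap-fill search horizon as a fraction of the
#'   region width/height (default 1: scan to the region edge).
#' @return A [TracedPath-class].
#' @export
tracePath <- function(clusters, curve_id, knn_k = 20, gap_horizon_frac = 1) {
  stopifnot(is(clusters, "CurveClusterSet"))
  px <- clusters@pixels
  cpx <- px[px$label == curve_id, , drop = FALSE]
  if (nrow(cpx) == 0L) kmStop("kmTraceError", "curve %d has no pixels", curve_id)
  r <- clusters@region
  dims <- c(r["rowMax"], r["colMax"])
  labmat <- .labelMatrix(px, dims)
  inCurve <- matrix(FALSE, dims[1], dims[2])
  inCurve[cbind(cpx$row, cpx$col)] <- TRUE
  scoreCache <- new.env(parent = emptyenv())
  score <- function(cc, rr) {
    key <- as.character(cc * (dims[1] + 1L) + rr)
    s <- scoreCache[[key]]
    if (is.null(s)) {
      s <- .knnScoreGrid(labmat, cc, rr, as.integer(curve_id),
                         as.integer(knn_k), warn = FALSE)
      scoreCache[[key]] <- s
    }
    s
  }
  hH <- max(1L, as.integer(round(gap_horizon_frac * (r["colMax"] - r["colMin"] + 1L))))
  hV <- max(1L, as.integer(round(gap_horizon_frac * (r["rowMax"] - r["rowMin"] + 1L))))
  # start: the curve's origin pixel - left-most, then top-most, and
  # coherent (positive knn score). A decreasing curve departs from its
  # top-left corner, so the leftmost column holds the true start, whereas
  # compression halos on other curves' lines accumulate at later times
  # and would capture a purely top-most start.
  ordPx <- order(cpx$col, cpx$row)
  cur <- NULL
  for (i in ordPx) {
    if (score(cpx$col[i], cpx$row[i]) > 0) {
      cur <- c(cpx$col[i], cpx$row[i])  # (col, row)
      break
    }
  }
  if (is.null(cur)) {
    cur <- c(cpx$col[ordPx[1L]], cpx$row[ordPx[1L]])
  }
  maxSteps <- (r["colMax"] - r["colMin"] + 2L) + (r["rowMax"] - r["rowMin"] + 2L)
  steps <- matrix(NA_integer_, maxSteps + 8L, 2L)
  steps[1L, ] <- cur
  nStep <- 1L
  push <- function(cc, rr) {
    nStep <<- nStep + 1L
    steps[nStep, ] <<- c(cc, rr)
  }
  repeat {
    cc <- steps[nStep, 1L]; rr <- steps[nStep, 2L]
    canRight <- cc + 1L <= r["colMax"] && inCurve[rr, cc + 1L]
    canDown  <- rr + 1L <= r["rowMax"] && inCurve[rr + 1L, cc]
    if (canRight && canDown) {
      if (score(cc + 1L, rr) >= score(cc, rr + 1L)) {
        push(cc + 1L, rr)
      } else {
        push(cc, rr + 1L)
      }
    } else if (canRight) {
      push(cc + 1L, rr)
    } else if (canDown) {
      push(cc, rr + 1L)
    } else {
      # gap fill: nearest column to the right holding a coherent curve
      # pixel at the same or lower height (positive knn score)
      found <- FALSE
      chi <- min(r["colMax"], cc + hH)
      if (cc < chi && rr <= r["rowMax"]) {
        for (c2 in (cc + 1L):chi) {
          colHit <- which(inCurve[rr:r["rowMax"], c2])
          for (hh in colHit) {
            r2 <- rr + hh - 1L
            if (score(c2, r2) > 0) {
              for (cf in (cc + 1L):c2) push(cf, rr)
              if (r2 > rr) for (rf in (rr + 1L):r2) push(c2, rf)
              found <- TRUE
              break
            }
          }
          if (found) break
        }
      }
      if (!found) {
        rhi <- min(r["rowMax"], rr + hV)
        if (rr < rhi) {
          for (hh in which(inCurve[(rr + 1L):rhi, cc])) {
            if (score(cc, rr + hh) > 0) {
              for (rf in (rr + 1L):(rr + hh)) push(cc, rf)
              found <- TRUE
              break
            }
          }
        }
      }
      if (!found) break
    }
    if (nStep >= maxSteps) break
  }
  new("TracedPath", curveId = as.integer(curve_id),
      steps = steps[seq_len(nStep), , drop = FALSE])
}
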