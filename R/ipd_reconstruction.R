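## Pseudo individual-patient-data reconstruction from a digitized curve
## and a number-at-risk table, in the spirit of the widely used
## digitized-curve heuristic: within each risk-table interval, integer
## event and censoring counts are solved so that the product-limit refit
## tracks the digitized survival levels and the number remaining at risk
## at each interval boundary matches the published table exactly.

.riskForGroup <- function(risk, group) {
  if ("group" %in% names(risk)) {
    risk <- risk[risk$group == group, , drop = FALSE]
  }
  risk <- risk[order(risk$time), , drop = FALSE]
  if (nrow(risk) == 0L) kmStop("kmInputError", "risk table empty for group")
  if (any(diff(risk$time) <= 0)) {
    kmStop("kmInputError", "risk-table times must be strictly increasing")
  }
  if (any(diff(risk$at_risk) > 0)) {
    kmStop("kmInputError", "at-risk counts must be non-increasing")
  }
  risk
}

.digitizedForGroup <- function(digitized, group) {
  d <- digitized
  if ("curve" %in% names(d)) d <- d[d$curve == group, , drop = FALSE]
  if (nrow(d) == 0L) kmStop("kmInputError", "no digitized rows for group")
  d <- d[order(d$time), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Match digitized rows to number-at-risk intervals
#'
#' For each consecutive pair of risk-table times `[T_j, T_(j+1))` the
#' interval covers the digitized rows whose time falls in it (left-closed,
#' right-open; the final interval is closed at the last digitized time).
#' `lower` and `upper` are 1-based row indices into the group's digitized
#' table; an interval with no rows has `upper = lower - 1`.
#'
#' @param digitized long curve table (`time`, `St`, optionally `curve`).
#' @param risk risk table with columns `time`, `at_risk` and optionally
#'   `group`.
#' @param group group/curve identifier used to filter both tables.
#' @return data.frame with `interval_id`, `lower`, `upper`, `n_risk`.
#' @export
buildIntervalTable <- function(digitized, risk, group = 1) {
  risk <- .riskForGroup(risk, group)
  d <- .digitizedForGroup(digitized, group)
  if (min(d$time) < risk$time[1]) {
    kmWarn("kmIntervalWarning",
           "digitized rows before the first risk time fall into interval 1")
  }
  J <- nrow(risk)
  lower <- upper <- integer(J)
  for (j in seq_len(J)) {
    lo <- if (j == 1L) -Inf else risk$time[j]
    hi <- if (j == J) Inf else risk$time[j + 1L]
    inside <- which(d$time >= lo & d$time < hi)
    if (length(inside)) {
      lower[j] <- min(inside); upper[j] <- max(inside)
    } else {
      lower[j] <- if (j == 1L) 1L else upper[j - 1L] + 1L
      upper[j] <- lower[j] - 1L
    }
  }
  data.frame(interval_id = seq_len(J), lower = lower, upper = upper,
             n_risk = risk$at_risk, time = risk$time)
}

#' Reconstruct pseudo individual patient data from a digitized curve
#'
#' Within each number-at-risk interval, the algorithm iterates on the
#' total number censored in the interval: censorings are spread evenly
#' over the digitized points of the interval (and in time, strictly
#' inside the interval), events at each digitized drop are the rounded
#' product-limit solution `d = round(n (1 - s/S))` against the running
#' reconstructed level `S`, and the censoring total is adjusted until the
#' number remaining at risk at the next boundary equals the published
#' count exactly. Subjects remaining after the last digitized point are
#' censored there (or assigned as events first when `total_events_known`
#' requires it).
#'
#' @param digitized long curve table (`time`, `St`, optionally `curve`).
#' @param intervals interval table from [buildIntervalTable()].
#' @param total_events_known optional total event count to honour.
#' @param group group label written to the output records.
#' @return data.frame (`time`, `status`, `group`): one row per
#'   reconstructed subject, status 1 = event, 0 = censored.
#' @export
reconstructIPD <- function(digitized, intervals, total_events_known = NULL,
                           group = 1) {
  d <- .digitizedForGroup(digitized, group)
  m <- nrow(d)
  J <- nrow(intervals)
  if (intervals$n_risk[1] <= 0) {
    kmStop("kmIpdError", "first interval has no subjects at risk")
  }
  tms <- d$time; sv <- d$St
  dEv <- integer(m); dCn <- integer(m)
  extras <- list()
  nCur <- intervals$n_risk[1]
  sEntry <- 1
  for (j in seq_len(J)) {
    if (intervals$upper[j] < intervals$lower[j]) {
      # no digitized rows: any at-risk loss is censoring inside the interval
      if (j < J) {
        loss <- nCur - intervals$n_risk[j + 1L]
        if (loss < 0) {
          kmStop("kmIpdError",
                 "infeasible risk counts in interval %d (risk grows)", j)
        }
        if (loss > 0) {
          extras[[length(extras) + 1L]] <- data.frame(
            time = intervals$time[j] +
              (intervals$time[j + 1L] - intervals$time[j]) *
              seq_len(loss) / (loss + 1L),
            status = 0L
          )
          nCur <- nCur - loss
        }
      }
      next
    }
    idx <- intervals$lower[j]:intervals$upper[j]
    len <- length(idx)
    bound <- if (j < J) intervals$time[j + 1L] else Inf
    target <- if (j < J) intervals$n_risk[j + 1L] else NA_integer_
    cTotal <- 0L
    best <- NULL
    for (iter in 1:60) {
      alloc <- diff(c(0L, round(seq_len(len) * cTotal / len)))
      n <- nCur; S <- sEntry
      dv <- integer(len); cv <- integer(len)
      for (ii in seq_len(len)) {
        i <- idx[ii]
        di <- if (n > 0L && S > 0) round(n * (1 - sv[i] / S)) else 0
        di <- as.integer(min(max(di, 0), n))
        if (n > 0L && di > 0L) S <- S * (1 - di / n)
        ci <- as.integer(min(alloc[ii], n - di))
        dv[ii] <- di; cv[ii] <- ci
        n <- n - di - ci
      }
      if (is.na(target)) { best <- list(dv = dv, cv = cv, n = n, S = S); break }
      diffN <- n - target
      if (is.null(best) || abs(diffN) < abs(best$diffN)) {
        best <- list(dv = dv, cv = cv, n = n, S = S, diffN = diffN)
      }
      if (diffN == 0L) break
      cTotal <- cTotal + diffN
      if (cTotal < 0L) {
        kmStop("kmIpdError", paste(
          "infeasible risk counts in interval %d:",
          "more subjects required at the next boundary than remain"
        ), j)
      }
    }
    dv <- best$dv; cv <- best$cv
    if (!is.na(target) && best$diffN != 0L) {
      # force exactness by adjusting censoring at the interval's last point
      adj <- best$diffN
      cv[len] <- cv[len] + adj
      if (cv[len] < 0L || sum(dv + cv) > nCur) {
        kmStop("kmIpdError", "infeasible risk counts in interval %d", j)
      }
      best$n <- best$n - adj
    }
    dEv[idx] <- dv; dCn[idx] <- cv
    nCur <- best$n
    sEntry <- best$S
  }
  # subjects remaining after the last digitized point
  tailEvents <- 0L
  if (!is.null(total_events_known)) {
    deficit <- as.integer(total_events_known) - sum(dEv)
    if (deficit > 0L) tailEvents <- min(deficit, nCur)
  }
  tailCens <- nCur - tailEvents

  rows <- list()
  boundary <- c(intervals$time[-1L], Inf)
  intervalOf <- findInterval(tms, intervals$time)
  for (i in seq_len(m)) {
    if (dEv[i] > 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        time = rep(tms[i], dEv[i]), status = 1L)
    }
    if (dCn[i] > 0L) {
      hi <- min(if (i < m) tms[i + 1L] else tms[m],
                boundary[max(intervalOf[i], 1L)])
      hi <- max(hi, tms[i])
      ct <- if (hi > tms[i]) {
        tms[i] + (hi - tms[i]) * seq_len(dCn[i]) / (dCn[i] + 1L)
      } else {
        rep(tms[i], dCn[i])
      }
      rows[[length(rows) + 1L]] <- data.frame(time = ct, status = 0L)
    }
  }
  if (tailEvents > 0L) {
    rows[[length(rows) + 1L]] <- data.frame(
      time = rep(tms[m], tailEvents), status = 1L)
  }
  if (tailCens > 0L) {
    rows[[length(rows) + 1L]] <- data.frame(
      time = rep(tms[m], tailCens), status = 0L)
  }
  out <- do.call(rbind, c(rows, extras))
  out <- out[order(out$time, -out$status), , drop = FALSE]
  out$group <- group
  rownames(out) <- NULL
  out
}

#' Refit a Kaplan-Meier curve from reconstructed records
#'
#' @param ipd data.frame (`time`, `status`, `group`) as produced by
#'   [reconstructIPD()].
#' @param group optional group filter.
#' @return A [StepFunction-class] product-limit estimate.
#' @export
refitKM <- function(ipd, group = NULL) {
  kmEstimate(ipd, group = group)
}

#' Reconstruct IPD for every group of a digitized table
#'
#' Convenience wrapper: builds the interval table and reconstructs
#' records for each distinct `curve` in the digitized table.
#'
#' @param digitized long curve table (`time`, `St`, `curve`).
#' @param risk risk table (`time`, `group`, `at_risk`).
#' @param total_events_known optional named vector of total events per
#'   group.
#' @return data.frame (`time`, `status`, `group`) over all groups.
#' @export
reconstructIPDFromTables <- function(digitized, risk,
                                     total_events_known = NULL) {
  groups <- sort(unique(digitized$curve))
  out <- lapply(groups, function(g) {
    iv <- buildIntervalTable(digitized, risk, group = g)
    tek <- if (!is.null(total_events_known)) {
      unname(total_events_known[as.character(g)])
    } else NULL
    reconstructIPD(digitized, iv, total_events_known = tek, group = g)
  })
  do.call(rbind, out)
}
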