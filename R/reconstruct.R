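#' Pseudo-IPD reconstruction from digitized Kaplan-Meier curves
#'
#' Implements the iterative curve-inversion algorithm of Guyot and
#' colleagues: given the digitized coordinates of a published KM curve and
#' its numbers-at-risk table, recover approximate patient-level event and
#' censoring times.  Censoring is assumed uniformly spread within each
#' inter-risk-table interval; within each interval the number censored is
#' adjusted until the implied number at risk matches the published table
#' at the next reporting time, and per-step death counts are recovered
#' from the successive survival ratios.
#'
#' @name km-reconstruction
NULL

#' Validate a digitized KM curve
#'
#' @param time,survival coordinate vectors; times nondecreasing starting
#'   at 0, survival nonincreasing in `[0, 1]` starting at 1.
#' @param arm arm label.
#' @return data frame `time`, `survival` of class `km_curve`.
#' @export
km_curve <- function(time, survival, arm = "") {
  stopifnot(length(time) == length(survival), length(time) >= 1)
  if (time[1] != 0 || survival[1] != 1) {
    stop("KM curve must start at (0, 1)", call. = FALSE)
  }
  if (is.unsorted(time)) stop("KM times must be nondecreasing", call. = FALSE)
  if (any(diff(survival) > 1e-9) || any(survival < 0 | survival > 1)) {
    stop("KM survival must be nonincreasing within [0, 1]", call. = FALSE)
  }
  structure(data.frame(time = as.numeric(time),
                       survival = as.numeric(survival)),
            arm = arm, class = c("km_curve", "data.frame"))
}

#' Validate a numbers-at-risk table
#'
#' @param time reporting times, strictly increasing.
#' @param n_at_risk nonincreasing nonnegative integer counts.
#' @return data frame of class `risk_table`.
#' @export
risk_table <- function(time, n_at_risk) {
  stopifnot(length(time) == length(n_at_risk), length(time) >= 1)
  if (is.unsorted(time, strictly = TRUE)) {
    stop("risk-table times must be strictly increasing", call. = FALSE)
  }
  if (any(n_at_risk < 0) || any(diff(n_at_risk) > 0)) {
    stop("risk-table counts must be nonincreasing and nonnegative",
         call. = FALSE)
  }
  structure(data.frame(time = as.numeric(time),
                       n_at_risk = as.integer(n_at_risk)),
            class = c("risk_table", "data.frame"))
}

#' Reconstruct pseudo individual-patient data (Guyot algorithm)
#'
#' Deterministic inversion of a digitized KM curve.  Within each interval
#' between consecutive risk-table times, censoring times are spread on an
#' even lattice and their number is increased or decreased until the
#' at-risk count implied by the reconstruction matches the published table
#' at the next reporting time; deaths at each digitized step are then the
#' rounded counts consistent with the published survival ratios.  Patients
#' still at risk past the last digitized coordinate are censored there.
#'
#' @param curve a [km_curve()] (or data frame `time`, `survival`).
#' @param risk a [risk_table()] (or data frame `time`, `n_at_risk`);
#'   its times must span the curve start.
#' @param total_events optional total number of deaths reported by the
#'   study; when supplied, censoring in the final interval is rescaled so
#'   reconstructed deaths match it.
#' @return a [pseudo_ipd()] with one record per reconstructed patient.
#' @export
reconstruct_ipd <- function(curve, risk, total_events = NULL) {
  if (!inherits(curve, "km_curve")) curve <- km_curve(curve$time, curve$survival)
  if (!inherits(risk, "risk_table")) risk <- risk_table(risk$time, risk$n_at_risk)
  t_S <- curve$time
  S <- curve$survival
  t_risk <- risk$time
  n_risk <- risk$n_at_risk
  # ensure every risk-table time has a curve coordinate: insert the
  # step-function value there (value-preserving, keeps intervals nonempty);
  # risk times beyond the last digitized point extend the curve flat, so
  # patients reported at risk there stay under observation until then
  for (tr in t_risk) {
    if (!any(abs(t_S - tr) < 1e-9)) {
      if (tr > max(t_S)) {
        t_S <- c(t_S, tr)
        S <- c(S, S[length(S)])
      } else {
        j <- max(which(t_S < tr))
        t_S <- append(t_S, tr, after = j)
        S <- append(S, S[j], after = j)
      }
    }
  }
  # keep only risk times within the digitized span (plus the curve end)
  keep <- t_risk <= max(t_S) + 1e-9
  t_risk <- t_risk[keep]; n_risk <- n_risk[keep]
  n_int <- length(t_risk)
  if (n_int < 1 || t_risk[1] > min(t_S) + 1e-9) {
    stop("risk table must span the start of the curve", call. = FALSE)
  }
  # lower[i]: first KM coordinate at/after risk time i; upper[i]: last before i+1
  lower <- vapply(t_risk, function(x) which(t_S >= x - 1e-9)[1], integer(1))
  upper <- c(lower[-1] - 1L, length(t_S))
  if (any(is.na(lower)) || any(upper < lower)) {
    stop("risk-table times not covered by curve coordinates", call. = FALSE)
  }
  n_t <- length(t_S)
  n_censor <- rep(0L, n_int)
  n_hat <- rep(n_risk[1] + 1, n_t + 1L)
  cen <- rep(0L, n_t)
  d <- rep(0L, n_t)
  KM_hat <- rep(1, n_t)
  last_i <- rep(1L, n_int + 1L)
  cen_times <- vector("list", n_int)

  run_interval <- function(i, nc) {
    # place nc censor times on an even lattice, bin them to KM steps,
    # then recover deaths from survival ratios; returns updated state
    lo <- lower[i]; up <- upper[i]
    end_t <- if (i < n_int) t_S[lower[i + 1]] else t_S[n_t]
    cen[lo:up] <<- 0L
    ct <- numeric(0)
    if (nc > 0) {
      ct <- t_S[lo] + seq_len(nc) * (end_t - t_S[lo]) / (nc + 1)
      brk <- c(t_S[lo:up], end_t)
      if (length(unique(brk)) > 1) {
        cnt <- graphics::hist(ct, breaks = unique(brk), plot = FALSE)$counts
        # map counts back to possibly-duplicated break positions
        idx <- match(t_S[lo:up], unique(brk)[-length(unique(brk))])
        cc <- rep(0L, up - lo + 1L)
        ok <- !is.na(idx)
        cc[ok] <- cnt[idx[ok]]
        cen[lo:up] <<- cc
      } else cen[lo] <<- nc
    }
    n_hat[lo] <<- n_risk[i]
    last <- last_i[i]
    for (k in lo:up) {
      if (k == 1) {
        d[k] <<- 0L
        KM_hat[k] <<- 1
      } else {
        ratio <- if (KM_hat[last] > 0) S[k] / KM_hat[last] else 1
        d[k] <<- round(n_hat[k] * (1 - ratio))
        if (d[k] < 0) d[k] <<- 0L
        if (d[k] > n_hat[k]) d[k] <<- n_hat[k]
        KM_hat[k] <<- if (n_hat[k] > 0) KM_hat[last] * (1 - d[k] / n_hat[k])
                      else KM_hat[last]
      }
      n_hat[k + 1] <<- n_hat[k] - d[k] - cen[k]
      if (d[k] != 0) last <- k
    }
    cen_times[[i]] <<- ct
    last
  }

  if (n_int > 1) {
    for (i in 1:(n_int - 1)) {
      # first guess from the survival ratio across the interval
      nc <- round(n_risk[i] * S[lower[i + 1]] / S[lower[i]]) - n_risk[i + 1]
      if (!is.finite(nc)) nc <- 0
      if (nc < 0) {
        warning("interval ", i, " (t = ", t_risk[i],
                "): negative implied censoring clamped to zero")
        nc <- 0
      }
      guard <- 0L
      repeat {
        nc <- max(nc, 0L)
        last <- run_interval(i, nc)
        gap <- n_hat[lower[i + 1]] - n_risk[i + 1]
        if (gap == 0 || (gap < 0 && nc == 0)) break
        nc <- nc + gap
        guard <- guard + 1L
        if (guard > 4L * n_risk[1] + 20L) {
          stop("reconstruction infeasible in interval ", i, " (t = ",
               t_risk[i], "): risk counts inconsistent with survival drops",
               call. = FALSE)
        }
      }
      n_censor[i] <- max(nc, 0L)
      if (n_hat[lower[i + 1]] < n_risk[i + 1]) {
        n_risk[i + 1] <- n_hat[lower[i + 1]]
      }
      last_i[i + 1] <- last
    }
  }
  # final interval: carry over the average censoring rate of earlier ones
  if (n_int > 1) {
    span_prev <- t_S[upper[n_int - 1]] - t_S[lower[1]]
    span_last <- t_S[upper[n_int]] - t_S[lower[n_int]]
    nc_last <- if (span_prev > 0)
      min(round(sum(n_censor[1:(n_int - 1)]) * span_last / span_prev),
          n_risk[n_int]) else 0L
  } else nc_last <- 0L
  n_censor[n_int] <- max(nc_last, 0L)
  run_interval(n_int, n_censor[n_int])

  if (!is.null(total_events)) {
    # rescale final-interval censoring until total deaths match
    guard <- 0L
    repeat {
      tot_d <- sum(d)
      if (tot_d == total_events || guard > 2L * n_risk[1] + 20L) break
      n_censor[n_int] <- max(n_censor[n_int] + sign(tot_d - total_events), 0L)
      run_interval(n_int, n_censor[n_int])
      if (n_censor[n_int] == 0L && sum(d) <= total_events) break
      guard <- guard + 1L
    }
  }

  # assemble records: deaths at step times, censorings at lattice times,
  # survivors censored at the last coordinate
  times <- c(rep(t_S, d), unlist(cen_times))
  events <- c(rep(1L, sum(d)), rep(0L, length(unlist(cen_times))))
  n_left <- n_hat[n_t + 1L]
  if (n_left > 0) {
    times <- c(times, rep(t_S[n_t], n_left))
    events <- c(events, rep(0L, n_left))
  }
  times <- pmax(times, .Machine$double.eps)
  ord <- order(times, -events)
  pseudo_ipd(times[ord], events[ord], attr(curve, "arm") %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bin reconstructed pseudo-IPD into labelled monthly interval counts
#'
#' Same counting contract as [interval_counts_from_ipd()], with study and
#' treatment labels attached so rows from several arms can be stacked into
#' the model's likelihood input.  The default 24-month horizon matches the
#' window over which both source trials still have patients at risk.
#'
#' @param ipd a [pseudo_ipd()].
#' @param study,treatment labels for the output rows.
#' @param horizon months, `> 0`.
#' @param width bin width in months.
#' @return data frame `study`, `treatment`, `interval_start`, `n_at_risk`,
#'   `deaths`, `censored`.
#' @export
bin_monthly <- function(ipd, study, treatment, horizon = 24, width = 1) {
  stopifnot(horizon > 0)
  out <- interval_counts_from_ipd(ipd, width = width, horizon = horizon)
  cbind(data.frame(study = study, treatment = treatment), out)
}
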