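#' Synthetic two-trial survival networks with known ground truth
#'
#' Emulates a pair of two-arm phase-3 trials sharing a common comparator
#' arm: uniform accrual over an accrual window, administrative censoring at
#' study cutoff, independent exponential loss to follow-up, and monthly
#' numbers-at-risk reporting.  Every downstream stage (reconstruction,
#' model fitting, reporting) can be validated against the generating
#' parameters.
#'
#' @name synthetic-trials
NULL

# run expr with a locally seeded RNG, restoring the caller's state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Specify one synthetic trial
#'
#' @param study_id study label.
#' @param arms list of arms, each a list with `treatment` (label),
#'   `n` (patients), `theta` (a [surv_param()] generating death times).
#' @param accrual_window months over which patients accrue uniformly.
#' @param max_followup study cutoff in months since first accrual; a
#'   patient accrued at offset `a` is administratively censored at
#'   `max_followup - a`.  May be `Inf`.
#' @param random_censor_rate per-month hazard of loss to follow-up
#'   (exponential, independent of death time); `0` disables it.
#' @param risk_table_times months at which the number at risk is reported;
#'   strictly increasing, starting at 0.
#' @return object of class `trial_spec`.
#' @export
trial_spec <- function(study_id, arms, accrual_window = 0,
                       max_followup = Inf, random_censor_rate = 0,
                       risk_table_times = 0:24) {
  stopifnot(length(arms) >= 1, accrual_window >= 0, max_followup > 0,
            random_censor_rate >= 0)
  if (risk_table_times[1] != 0 || is.unsorted(risk_table_times, strictly = TRUE)) {
    stop("risk_table_times must start at 0 and be strictly increasing",
         call. = FALSE)
  }
  for (a in arms) {
    stopifnot(is.character(a$treatment), a$n >= 0,
              inherits(a$theta, "surv_param"))
  }
  structure(list(study_id = study_id, arms = arms,
                 accrual_window = accrual_window,
                 max_followup = max_followup,
                 random_censor_rate = random_censor_rate,
                 risk_table_times = risk_table_times),
            class = "trial_spec")
}

#' Pseudo individual-patient data container
#'
#' A data frame with columns `time` (months, `> 0`) and `event`
#' (1 = death, 0 = censored), carrying an `arm` attribute.
#'
#' @param time,event numeric vectors of equal length.
#' @param arm arm label.
#' @export
pseudo_ipd <- function(time, event, arm = "") {
  stopifnot(length(time) == length(event), all(is.finite(time)),
            all(time > 0 | length(time) == 0), all(event %in% c(0, 1)))
  structure(data.frame(time = as.numeric(time), event = as.integer(event)),
            arm = arm, class = c("pseudo_ipd", "data.frame"))
}

#' Simulate one trial arm
#'
#' Death times are drawn from the arm's family/theta by inverse-CDF;
#' the observed time is the minimum of death time, random censoring time
#' and administrative cutoff (`max_followup` minus the uniform accrual
#' offset).
#'
#' @param arm a list with `treatment`, `n`, `theta` (see [trial_spec()]).
#' @param accrual_window,max_followup,censor_rate see [trial_spec()].
#' @param seed optional integer; RNG state is restored afterwards.
#' @return a [pseudo_ipd()] with one record per patient.
#' @export
simulate_arm <- function(arm, accrual_window = 0, max_followup = Inf,
                         censor_rate = 0, seed = NULL) {
  stopifnot(inherits(arm$theta, "surv_param"), arm$n >= 0)
  with_seed(seed, {
    n <- as.integer(arm$n)
    if (n == 0L) return(pseudo_ipd(numeric(0), integer(0), arm$treatment))
    death <- r_surv_time(arm$theta, n)
    loss <- if (censor_rate > 0) stats::rexp(n, censor_rate) else rep(Inf, n)
    accrual <- if (accrual_window > 0) stats::runif(n, 0, accrual_window)
               else rep(0, n)
    admin <- max_followup - accrual
    cens <- pmin(loss, admin)
    time <- pmin(death, cens)
    event <- as.integer(death <= cens)
    # guard against exact-zero observed times (admin = 0 edge)
    time <- pmax(time, .Machine$double.eps)
    pseudo_ipd(time, event, arm$treatment)
  })
}

#' Product-limit curve and risk table from pseudo-IPD
#'
#' Computes the Kaplan-Meier estimate as a right-continuous step function
#' (coordinates: time 0 at survival 1, then one point per distinct death
#' time at the post-drop value) and the number still under observation at
#' each scheduled reporting time.
#'
#' @param ipd a [pseudo_ipd()].
#' @param risk_table_times reporting times in months.
#' @return list with `curve` (data frame `time`, `survival`) and
#'   `risk` (data frame `time`, `n_at_risk`).
#' @export
km_from_ipd <- function(ipd, risk_table_times = 0:24) {
  stopifnot(nrow(ipd) > 0)
  ord <- order(ipd$time)
  tm <- ipd$time[ord]; ev <- ipd$event[ord]
  dt <- sort(unique(tm[ev == 1]))
  surv <- 1
  s <- numeric(length(dt))
  for (j in seq_along(dt)) {
    at_risk <- sum(tm >= dt[j])
    d <- sum(tm == dt[j] & ev == 1)
    surv <- surv * (1 - d / at_risk)
    s[j] <- surv
  }
  curve <- data.frame(time = c(0, dt), survival = c(1, s))
  risk <- data.frame(time = risk_table_times,
                     n_at_risk = vapply(risk_table_times,
                                        function(x) sum(tm >= x), integer(1)))
  list(curve = curve, risk = risk)
}

#' Monthly interval counts from pseudo-IPD
#'
#' Bins events and censorings into half-open intervals
#' `[j * width, (j + 1) * width)`; the at-risk count at the start of each
#' interval follows the bookkeeping identity
#' `n(j + 1) = n(j) - deaths(j) - censored(j)`.  Records at or beyond the
#' horizon contribute to no interval (they remain at risk throughout).
#'
#' @param ipd a [pseudo_ipd()] (may be empty).
#' @param width interval width in months, `> 0`.
#' @param horizon last month covered; the table has
#'   `ceiling(horizon / width)` rows.
#' @return data frame `interval_start`, `n_at_risk`, `deaths`, `censored`.
#' @export
interval_counts_from_ipd <- function(ipd, width = 1, horizon = 24) {
  stopifnot(width > 0, horizon > 0)
  nint <- ceiling(horizon / width)
  starts <- (seq_len(nint) - 1) * width
  d <- integer(nint); cns <- integer(nint); n <- integer(nint)
  at_risk <- nrow(ipd)
  for (j in seq_len(nint)) {
    lo <- starts[j]; hi <- lo + width
    n[j] <- at_risk
    sel <- ipd$time >= lo & ipd$time < hi
    d[j] <- sum(sel & ipd$event == 1)
    cns[j] <- sum(sel & ipd$event == 0)
    at_risk <- at_risk - d[j] - cns[j]
  }
  data.frame(interval_start = starts, n_at_risk = n, deaths = d,
             censored = cns)
}

#' Default two-trial synthetic scenario
#'
#' Mirrors the structure of the motivating indirect comparison in advanced
#' renal-cell carcinoma: two phase-3 trials sharing an everolimus control
#' arm, one adding nivolumab (821 patients total) and one adding
#' cabozantinib (658 patients), log-logistic event times with an
#' everolimus median of 19.6 months, and treatment effects chosen so the
#' true nivolumab-vs-cabozantinib hazard ratio crosses 1 near month 5
#' (cabozantinib favoured earlier, nivolumab later).
#'
#' @param n_per_arm optional common per-arm size overriding the
#'   trial-specific defaults (used by validation studies at n = 400).
#' @return list of two [trial_spec()]s plus the generating `truth`
#'   (family, baselines, transformed-scale effect vectors).
#' @export
default_scenario <- function(n_per_arm = NULL) {
  fam <- surv_family("loglogistic")
  ever <- surv_param(fam, c(19.6, 1.30))
  # medians 25 / 21.05 months; true HR(nivolumab vs cabozantinib) = 1 at month 5
  delta_niv <- c(log(25.00) - log(19.6), log(1.000) - log(1.30))
  delta_cab <- c(log(21.05) - log(19.6), log(1.382) - log(1.30))
  n1 <- if (is.null(n_per_arm)) c(411L, 410L) else rep(n_per_arm, 2)
  n2 <- if (is.null(n_per_arm)) c(329L, 329L) else rep(n_per_arm, 2)
  s1 <- trial_spec(
    study_id = "motzer_like",
    arms = list(
      list(treatment = "everolimus", n = n1[1], theta = ever),
      list(treatment = "nivolumab", n = n1[2],
           theta = apply_effect(ever, delta_niv))),
    accrual_window = 13, max_followup = 32,
    random_censor_rate = 0.002, risk_table_times = 0:26)
  s2 <- trial_spec(
    study_id = "choueiri_like",
    arms = list(
      list(treatment = "everolimus", n = n2[1], theta = ever),
      list(treatment = "cabozantinib", n = n2[2],
           theta = apply_effect(ever, delta_cab))),
    accrual_window = 11, max_followup = 25,
    random_censor_rate = 0.002, risk_table_times = 0:24)
  list(trials = list(s1, s2),
       truth = list(family = fam$name,
                    baseline = ever,
                    delta = list(nivolumab = delta_niv,
                                 cabozantinib = delta_cab)))
}

#' Simulate a full scenario into trial-level artifacts
#'
#' For every arm of every trial: pseudo-IPD, digitized-style KM curve,
#' monthly risk table and monthly interval counts.
#'
#' @param scenario as returned by [default_scenario()].
#' @param seed integer seed (mandatory: the generator is stochastic).
#' @param horizon binning horizon in months.
#' @return list of per-arm records, each with `study`, `treatment`, `ipd`,
#'   `curve`, `risk`, `intervals`.
#' @export
simulate_scenario <- function(scenario = default_scenario(), seed,
                              horizon = 24) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  out <- list()
  with_seed(seed, {
    for (tr in scenario$trials) {
      for (arm in tr$arms) {
        ipd <- simulate_arm(arm, tr$accrual_window, tr$max_followup,
                            tr$random_censor_rate)
        km <- km_from_ipd(ipd, tr$risk_table_times)
        iv <- interval_counts_from_ipd(ipd, width = 1, horizon = horizon)
        iv$study <- tr$study_id
        iv$treatment <- arm$treatment
        out[[length(out) + 1L]] <- list(study = tr$study_id,
                                        treatment = arm$treatment,
                                        ipd = ipd, curve = km$curve,
                                        risk = km$risk, intervals = iv)
      }
    }
  })
  out
}
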