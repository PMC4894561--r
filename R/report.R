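#' Posterior summaries and the classical indirect comparison
#'
#' Turns posterior draws into the reporting outputs of the analysis:
#' time-varying hazard-ratio series with credible intervals,
#' reference-study-adjusted absolute survival curves, per-time-point
#' probability of being the best treatment, and the Bucher indirect
#' comparison computed from published summary hazard ratios.
#'
#' @name effects-reporting
NULL

#' Bucher indirect comparison from reported hazard ratios
#'
#' Two treatments compared against a common comparator in separate trials:
#' the indirect HR is the ratio of the reported HRs, and the log-scale
#' standard errors recovered from each trial's confidence interval
#' (honouring its stated confidence level) combine in quadrature.
#'
#' @param hr_a,hr_b reported hazard ratios (each vs the common comparator).
#' @param ci_a,ci_b length-2 confidence bounds `(lower, upper)`.
#' @param level_a,level_b confidence levels of the reported intervals.
#' @return list with `hr`, `ci95` (95% bounds), `log_se`.
#' @examples
#' bucher_indirect(0.73, c(0.57, 0.93), 0.985, 0.67, c(0.51, 0.89), 0.95)
#' @export
bucher_indirect <- function(hr_a, ci_a, level_a = 0.95,
                            hr_b, ci_b, level_b = 0.95) {
  stopifnot(hr_a > 0, hr_b > 0, all(ci_a > 0), all(ci_b > 0),
            level_a > 0, level_a < 1, level_b > 0, level_b < 1)
  if (ci_a[1] > ci_a[2] || ci_b[1] > ci_b[2]) {
    stop("confidence bounds must be (lower, upper)", call. = FALSE)
  }
  z_a <- stats::qnorm(1 - (1 - level_a) / 2)
  z_b <- stats::qnorm(1 - (1 - level_b) / 2)
  se_a <- (log(ci_a[2]) - log(ci_a[1])) / (2 * z_a)
  se_b <- (log(ci_b[2]) - log(ci_b[1])) / (2 * z_b)
  se <- sqrt(se_a^2 + se_b^2)
  hr <- hr_a / hr_b
  z95 <- stats::qnorm(0.975)
  list(hr = hr,
       ci95 = c(exp(log(hr) - z95 * se), exp(log(hr) + z95 * se)),
       log_se = se)
}

#' Odds of being the best treatment
#'
#' @param p probability in `[0, 1)`.
#' @return `p / (1 - p)`.
#' @export
odds_best <- function(p) {
  stopifnot(all(p >= 0))
  if (any(p >= 1)) stop("odds undefined at p = 1", call. = FALSE)
  p / (1 - p)
}

# transformed-scale parameter matrix (draws x dim) of `treatment`
# adjusted to `study`'s baseline: mu_study + d_trt - d_study_ref_arm
draw_eta <- function(draws, study, treatment) {
  model <- draws$model
  stacked <- stack_draws(draws)
  dim <- model$dim
  si <- match(study, model$studies)
  if (is.na(si)) stop("unknown study '", study, "'", call. = FALSE)
  if (!(treatment %in% model$treatments)) {
    stop("unknown treatment '", treatment, "'", call. = FALSE)
  }
  eta <- stacked[, (si - 1) * dim + seq_len(dim), drop = FALSE]
  dcols <- function(trt) {
    j <- match(trt, model$non_ref)
    if (is.na(j)) matrix(0, nrow(stacked), dim)
    else stacked[, length(model$studies) * dim + (j - 1) * dim + seq_len(dim),
                 drop = FALSE]
  }
  eta + dcols(treatment) - dcols(model$study_ref[[study]])
}

# vectorized hazard over transformed-scale draws at scalar time t
haz_eta <- function(family, eta, t) {
  switch(family,
    exponential = exp(eta[, 1]),
    weibull     = {
      lam <- exp(eta[, 1]); k <- exp(eta[, 2])
      lam * k * t^(k - 1)
    },
    gompertz    = exp(eta[, 1]) * exp(eta[, 2] * t),
    loglogistic = {
      a <- exp(eta[, 1]); b <- exp(eta[, 2])
      x <- (t / a)^b
      (b / a) * (t / a)^(b - 1) / (1 + x)
    })
}

# vectorized survival over transformed-scale draws at scalar time t
surv_eta <- function(family, eta, t) {
  switch(family,
    exponential = exp(-exp(eta[, 1]) * t),
    weibull     = exp(-exp(eta[, 1]) * t^exp(eta[, 2])),
    gompertz    = {
      lam <- exp(eta[, 1]); g <- eta[, 2]
      ch <- ifelse(abs(g) < 1e-12, lam * t, lam * expm1(g * t) / g)
      exp(-ch)
    },
    loglogistic = 1 / (1 + (t / exp(eta[, 1]))^exp(eta[, 2])))
}

#' Posterior hazard-ratio series over a time grid
#'
#' Per draw, the hazard ratio of `pair[1]` vs `pair[2]` evaluated on
#' parameters adjusted to `baseline_study`; summaries are pointwise
#' posterior quantiles.  For the exponential family the series is
#' constant (proportional hazards).
#'
#' @param draws an [nma_fit()] result.
#' @param pair character vector of two treatments, numerator first.
#' @param grid months (`> 0`, within the modelled horizon).
#' @param baseline_study study whose baseline anchors the non-PH families;
#'   defaults to the first study in the model.
#' @return data frame `time`, `mean`, `median`, `lo50`, `hi50`, `lo95`,
#'   `hi95`.
#' @export
hr_series <- function(draws, pair, grid = 1:24, baseline_study = NULL) {
  stopifnot(inherits(draws, "nma_draws"), length(pair) == 2)
  if (any(grid <= 0)) stop("grid must be positive times", call. = FALSE)
  model <- draws$model
  if (is.null(baseline_study)) baseline_study <- model$studies[1]
  fam <- model$family$name
  eta_a <- draw_eta(draws, baseline_study, pair[1])
  eta_b <- draw_eta(draws, baseline_study, pair[2])
  rows <- lapply(grid, function(t) {
    hb <- haz_eta(fam, eta_b, t)
    ha <- haz_eta(fam, eta_a, t)
    if (any(!is.finite(ha)) || any(!is.finite(hb)) || any(hb == 0)) {
      stop("hazard undefined at grid point t = ", t, call. = FALSE)
    }
    hr <- ha / hb
    q <- stats::quantile(hr, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE)
    data.frame(time = t, mean = mean(hr), median = q[3],
               lo50 = q[2], hi50 = q[4], lo95 = q[1], hi95 = q[5])
  })
  do.call(rbind, rows)
}

#' Reference-study-adjusted absolute survival curves
#'
#' Absolute survival for each treatment anchored to one study's baseline:
#' per draw, `S(t)` under `mu_reference_study` shifted by the treatment's
#' effect vector; summarized pointwise with 95% credible bands.
#'
#' @param draws an [nma_fit()] result.
#' @param reference_study study providing the baseline parameters.
#' @param treatments treatments to report (default: all in the network).
#' @param grid months, `>= 0`.
#' @return data frame `treatment`, `time`, `mean`, `median`, `lo95`,
#'   `hi95`.
#' @export
adjusted_survival <- function(draws, reference_study = NULL,
                              treatments = NULL, grid = 0:24) {
  stopifnot(inherits(draws, "nma_draws"))
  model <- draws$model
  if (is.null(reference_study)) reference_study <- model$studies[1]
  if (!(reference_study %in% model$studies)) {
    stop("reference_study '", reference_study, "' not in fitted network",
         call. = FALSE)
  }
  if (is.null(treatments)) treatments <- model$treatments
  fam <- model$family$name
  out <- lapply(treatments, function(trt) {
    eta <- draw_eta(draws, reference_study, trt)
    rows <- lapply(grid, function(t) {
      s <- surv_eta(fam, eta, t)
      q <- stats::quantile(s, c(0.025, 0.5, 0.975), names = FALSE)
      data.frame(treatment = trt, time = t, mean = mean(s),
                 median = q[2], lo95 = q[1], hi95 = q[3])
    })
    do.call(rbind, rows)
  })
  do.call(rbind, out)
}

#' Probability of being the best treatment over time
#'
#' At each grid point, the fraction of posterior draws in which each
#' treatment attains the strictly largest adjusted survival; exact ties
#' are split equally among the tied treatments.
#'
#' @inheritParams adjusted_survival
#' @return data frame `time` plus one probability column per treatment;
#'   rows sum to 1.
#' @export
prob_best <- function(draws, reference_study = NULL, treatments = NULL,
                      grid = 1:24) {
  stopifnot(inherits(draws, "nma_draws"))
  model <- draws$model
  if (is.null(reference_study)) reference_study <- model$studies[1]
  if (is.null(treatments)) treatments <- model$treatments
  if (length(treatments) < 2) stop("need at least 2 treatments", call. = FALSE)
  fam <- model$family$name
  etas <- lapply(treatments, function(trt)
    draw_eta(draws, reference_study, trt))
  rows <- lapply(grid, function(t) {
    S <- vapply(etas, function(e) surv_eta(fam, e, t),
                numeric(nrow(etas[[1]])))
    mx <- do.call(pmax, as.data.frame(S))
    is_top <- S == mx
    wt <- is_top / rowSums(is_top)          # ties split equally
    p <- colMeans(wt)
    stats::setNames(data.frame(t(c(t, p))), c("time", treatments))
  })
  do.call(rbind, rows)
}

#' Table-style export of hazard ratios at the usual reporting cadence
#'
#' @param series an [hr_series()] result.
#' @param at months to keep (default every 3 months up to the grid end).
#' @return subset of `series` with columns formatted for export.
#' @export
hr_table <- function(series, at = seq(3, max(series$time), by = 3)) {
  series[series$time %in% at, , drop = FALSE]
}
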