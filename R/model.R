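#' Fixed-effect parametric survival network model
#'
#' One baseline parameter vector per study (the transformed-scale
#' parameters of that study's reference arm) plus one effect vector per
#' non-reference treatment, shared across studies.  The likelihood is
#' binomial on monthly interval counts: in each interval, deaths among
#' those at risk (minus the interval's censored patients) occur with the
#' family's conditional death probability `1 - S(t1)/S(t0)`.
#'
#' @name network-model
NULL

#' Normal prior specification for transformed-scale parameters
#'
#' @param sd standard deviation of the independent zero-mean normal prior
#'   placed on every baseline and effect parameter (transformed scale).
#' @export
prior_normal <- function(sd = 10) {
  stopifnot(sd > 0)
  structure(list(mean = 0, sd = sd), class = "nma_prior")
}

#' Build a network model from stacked interval counts
#'
#' @param data data frame with columns `study`, `treatment`,
#'   `interval_start`, `n_at_risk`, `deaths`, `censored` (as produced by
#'   [bin_monthly()]), covering at least one study with two or more arms.
#' @param family family name or [surv_family()].
#' @param priors a [prior_normal()].
#' @param ref_treatment network reference treatment (effect fixed at 0);
#'   defaults to the treatment appearing in the most studies (the common
#'   comparator).
#' @param study_ref optional named character vector mapping study labels
#'   to that study's baseline arm; defaults to `ref_treatment` where
#'   present, else the study's first arm.  The parametrization of an arm
#'   is `mu_study + d_treatment - d_baseline_arm`, so relabeling the
#'   baseline arm leaves all between-treatment contrasts invariant.
#' @param censor_adjust `"full"` removes all patients censored within an
#'   interval from the binomial denominator; `"half"` removes half
#'   (actuarial correction).
#' @param width interval width in months.
#' @return object of class `nma_model`.
#' @export
build_model <- function(data, family, priors = prior_normal(),
                        ref_treatment = NULL, study_ref = NULL,
                        censor_adjust = c("full", "half"), width = 1) {
  fam <- surv_family(family)
  censor_adjust <- match.arg(censor_adjust)
  need <- c("study", "treatment", "interval_start", "n_at_risk",
            "deaths", "censored")
  if (!all(need %in% names(data))) {
    stop("data must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  data$study <- as.character(data$study)
  data$treatment <- as.character(data$treatment)
  studies <- unique(data$study)
  arms_by_study <- lapply(studies, function(s)
    unique(data$treatment[data$study == s]))
  names(arms_by_study) <- studies
  if (any(lengths(arms_by_study) < 2)) {
    stop("every study needs at least two arms", call. = FALSE)
  }
  treatments <- unique(data$treatment)
  # connectivity: union-find over treatments joined within studies
  parent <- stats::setNames(treatments, treatments)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (arms in arms_by_study) {
    r <- find(arms[1])
    for (a in arms[-1]) parent[[find(a)]] <- r
  }
  roots <- vapply(treatments, find, character(1))
  if (length(unique(roots)) > 1) {
    comps <- split(treatments, roots)
    stop("treatment network is disconnected; components: ",
         paste(vapply(comps, paste, "", collapse = "+"), collapse = " | "),
         call. = FALSE)
  }
  if (is.null(ref_treatment)) {
    n_stud <- vapply(treatments, function(tr)
      sum(vapply(arms_by_study, function(a) tr %in% a, logical(1))), integer(1))
    ref_treatment <- treatments[which.max(n_stud)]
  }
  stopifnot(ref_treatment %in% treatments)
  if (is.null(study_ref)) {
    study_ref <- vapply(studies, function(s)
      if (ref_treatment %in% arms_by_study[[s]]) ref_treatment
      else arms_by_study[[s]][1], character(1))
  }
  stopifnot(all(names(study_ref) %in% studies) || length(names(study_ref)) == 0)
  if (is.null(names(study_ref))) names(study_ref) <- studies
  for (s in studies) {
    if (!(study_ref[[s]] %in% arms_by_study[[s]])) {
      stop("study '", s, "' does not contain its reference arm '",
           study_ref[[s]], "'", call. = FALSE)
    }
  }
  dim <- fam$dim
  non_ref <- setdiff(treatments, ref_treatment)
  par_names <- c(
    as.vector(t(outer(studies, fam$par_names,
                      function(s, p) paste0("mu[", s, ",", p, "]")))),
    if (length(non_ref))
      as.vector(t(outer(non_ref, fam$par_names,
                        function(k, p) paste0("d[", k, ",", p, "]")))))
  npar <- length(par_names)
  # precompute row-level indexing for the vectorized likelihood
  size <- switch(censor_adjust,
                 full = data$n_at_risk - data$censored,
                 half = round(data$n_at_risk - data$censored / 2))
  if (any(size < data$deaths)) {
    stop("deaths exceed binomial denominator in some rows", call. = FALSE)
  }
  keep <- size > 0
  rows <- data[keep, , drop = FALSE]
  size <- size[keep]
  study_idx <- match(rows$study, studies)
  trt_idx <- match(rows$treatment, treatments)
  ref_trt_idx <- match(study_ref[rows$study], treatments)
  lchoose_const <- lchoose(size, rows$deaths)
  structure(list(
    family = fam, priors = priors, studies = studies,
    treatments = treatments, ref_treatment = ref_treatment,
    study_ref = study_ref, non_ref = non_ref, dim = dim,
    par_names = par_names, npar = npar, width = width,
    censor_adjust = censor_adjust, data = data,
    rows = rows, size = size, study_idx = study_idx,
    trt_idx = trt_idx, ref_trt_idx = ref_trt_idx,
    lchoose_const = lchoose_const), class = "nma_model")
}

#' @export
print.nma_model <- function(x, ...) {
  cat("<nma_model> family:", x$family$name, "|", length(x$studies),
      "studies,", length(x$treatments), "treatments,", x$npar,
      "parameters,", nrow(x$rows), "likelihood rows\n")
  invisible(x)
}

# transformed-scale parameters of every (study, treatment) arm for one
# parameter vector: matrix arms x dim
arm_eta <- function(model, par) {
  dim <- model$dim
  ns <- length(model$studies)
  mu <- matrix(par[seq_len(ns * dim)], ncol = dim, byrow = TRUE)
  dmat <- matrix(0, length(model$treatments), dim)
  if (length(model$non_ref)) {
    dd <- matrix(par[ns * dim + seq_len(length(model$non_ref) * dim)],
                 ncol = dim, byrow = TRUE)
    dmat[match(model$non_ref, model$treatments), ] <- dd
  }
  list(mu = mu, dmat = dmat)
}

#' Log-likelihood of a parameter vector under the network model
#'
#' Binomial log-likelihood (including the combinatorial constant) over
#' all interval rows.
#'
#' @param model an [build_model()] result.
#' @param par numeric vector of length `model$npar` (transformed scale,
#'   order `model$par_names`).
#' @export
nma_loglik <- function(model, par) {
  stopifnot(length(par) == model$npar)
  if (any(!is.finite(par))) return(-Inf)
  p <- arm_eta(model, par)
  rows <- model$rows
  dim <- model$dim
  # eta per row: mu_study + d_trt - d_study_ref_arm
  eta <- p$mu[model$study_idx, , drop = FALSE] +
    p$dmat[model$trt_idx, , drop = FALSE] -
    p$dmat[model$ref_trt_idx, , drop = FALSE]
  t0 <- rows$interval_start
  t1 <- t0 + model$width
  # family-specific conditional death probability, vectorized over rows
  pdie <- switch(model$family$name,
    exponential = {
      lam <- exp(eta[, 1])
      1 - exp(-lam * model$width)
    },
    weibull = {
      lam <- exp(eta[, 1]); k <- exp(eta[, 2])
      1 - exp(-lam * (t1^k - t0^k))
    },
    gompertz = {
      lam <- exp(eta[, 1]); g <- eta[, 2]
      ch <- ifelse(abs(g) < 1e-12, lam * model$width,
                   lam * (exp(g * t1) - exp(g * t0)) / g)
      1 - exp(-ch)
    },
    loglogistic = {
      a <- exp(eta[, 1]); b <- exp(eta[, 2])
      1 - (1 + (t0 / a)^b) / (1 + (t1 / a)^b)
    })
  if (any(!is.finite(pdie))) return(-Inf)
  pdie <- pmin(pmax(pdie, 1e-300), 1 - 1e-12)
  sum(model$lchoose_const + rows$deaths * log(pdie) +
        (model$size - rows$deaths) * log1p(-pdie))
}

nma_logprior <- function(model, par) {
  sum(stats::dnorm(par, model$priors$mean, model$priors$sd, log = TRUE))
}

nma_logpost <- function(model, par) {
  lp <- nma_logprior(model, par)
  if (!is.finite(lp)) return(-Inf)
  ll <- nma_loglik(model, par)
  if (!is.finite(ll)) return(-Inf)
  lp + ll
}

# crude data-driven initial values on the transformed scale
nma_init <- function(model) {
  par <- numeric(model$npar)
  dim <- model$dim
  for (si in seq_along(model$studies)) {
    s <- model$studies[si]
    sel <- model$rows$study == s & model$rows$treatment == model$study_ref[[s]]
    d <- sum(model$rows$deaths[sel])
    pt <- sum(model$size[sel]) * model$width   # person-months, coarse
    rate <- max(d, 0.5) / max(pt, 1)
    base <- switch(model$family$name,
      exponential = log(rate),
      weibull     = c(log(rate), 0),
      gompertz    = c(log(rate), 0),
      loglogistic = c(log(log(2) / rate), 0))  # scale ~ median of matched exp
    par[(si - 1) * dim + seq_len(dim)] <- base
  }
  par
}
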