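#' Parametric survival families
#'
#' Four families are supported: exponential (one parameter), Weibull,
#' Gompertz and log-logistic (two parameters each).  Treatment effects act
#' additively on the *transformed* scale: log for every
#' positivity-constrained parameter and identity for the Gompertz shape,
#' which may be negative.
#'
#' Parametrizations (t in months):
#' \describe{
#'   \item{exponential}{rate \eqn{\lambda}: \eqn{S(t) = e^{-\lambda t}}.}
#'   \item{weibull}{rate \eqn{\lambda}, shape \eqn{k}:
#'     \eqn{S(t) = e^{-\lambda t^k}} (exponential is the \eqn{k = 1} sub-case).}
#'   \item{gompertz}{rate \eqn{\lambda}, shape \eqn{\gamma}:
#'     \eqn{S(t) = \exp\{-(\lambda/\gamma)(e^{\gamma t} - 1)\}}, with the
#'     exponential limit as \eqn{\gamma \to 0}.}
#'   \item{loglogistic}{scale \eqn{\alpha} (the median, in months), shape
#'     \eqn{\beta}: \eqn{S(t) = 1/(1 + (t/\alpha)^\beta)}.}
#' }
#'
#' @param name one of `"exponential"`, `"weibull"`, `"gompertz"`,
#'   `"loglogistic"`.
#' @return an object of class `surv_family` with elements `name`, `dim`,
#'   `par_names` and `transform` (per-parameter link labels).
#' @examples
#' fam <- surv_family("weibull")
#' fam$dim
#' @export
surv_family <- function(name) {
  if (inherits(name, "surv_family")) return(name)
  allowed <- c("exponential", "weibull", "gompertz", "loglogistic")
  if (!is.character(name) || length(name) != 1L || !(name %in% allowed)) {
    stop("unknown family '", paste(name, collapse = ","),
         "'; allowed families: ", paste(allowed, collapse = ", "),
         call. = FALSE)
  }
  info <- switch(name,
    exponential = list(dim = 1L, par_names = "rate",
                       transform = "log"),
    weibull     = list(dim = 2L, par_names = c("rate", "shape"),
                       transform = c("log", "log")),
    gompertz    = list(dim = 2L, par_names = c("rate", "shape"),
                       transform = c("log", "identity")),
    loglogistic = list(dim = 2L, par_names = c("scale", "shape"),
                       transform = c("log", "log")))
  structure(c(list(name = name), info), class = "surv_family")
}

#' Natural-scale parameter vector for a survival family
#'
#' @param family family name or `surv_family` object.
#' @param values numeric vector on the natural scale, length `family$dim`.
#' @return object of class `surv_param`.
#' @examples
#' surv_param("loglogistic", c(scale = 19.6, shape = 1.3))
#' @export
surv_param <- function(family, values) {
  fam <- surv_family(family)
  values <- as.numeric(values)
  if (length(values) != fam$dim) {
    stop("family '", fam$name, "' needs ", fam$dim, " parameter(s), got ",
         length(values), call. = FALSE)
  }
  if (any(!is.finite(values))) stop("non-finite parameter values", call. = FALSE)
  pos <- fam$transform == "log"
  if (any(values[pos] <= 0)) {
    stop("parameter(s) ", paste(fam$par_names[pos][values[pos] <= 0],
                                collapse = ", "),
         " must be positive for family '", fam$name, "'", call. = FALSE)
  }
  names(values) <- fam$par_names
  structure(list(family = fam, values = values), class = "surv_param")
}

#' @export
print.surv_param <- function(x, ...) {
  cat("<surv_param ", x$family$name, "> ",
      paste(names(x$values), signif(x$values, 4), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# map natural-scale values to the transformed (effect) scale and back
#' @rdname surv_param
#' @param theta a `surv_param`.
#' @export
to_transformed <- function(theta) {
  stopifnot(inherits(theta, "surv_param"))
  out <- theta$values
  is_log <- theta$family$transform == "log"
  out[is_log] <- log(out[is_log])
  out
}

#' @rdname surv_param
#' @param eta numeric vector on the transformed scale.
#' @export
from_transformed <- function(family, eta) {
  fam <- surv_family(family)
  vals <- as.numeric(eta)
  is_log <- fam$transform == "log"
  vals[is_log] <- exp(vals[is_log])
  surv_param(fam, vals)
}

#' Survival function S(t)
#'
#' @param theta a [surv_param()].
#' @param t time in months, vectorized, must be `>= 0`.
#' @return survival probabilities in `[0, 1]`.
#' @export
surv_prob <- function(theta, t) {
  stopifnot(inherits(theta, "surv_param"))
  if (any(t < 0)) stop("negative time in surv_prob()", call. = FALSE)
  v <- theta$values
  switch(theta$family$name,
    exponential = exp(-v[[1]] * t),
    weibull     = exp(-v[[1]] * t^v[[2]]),
    gompertz    = {
      g <- v[[2]]
      # (e^{g t} - 1)/g -> t as g -> 0; expm1 keeps this stable
      cumhaz <- if (abs(g) < 1e-12) v[[1]] * t else v[[1]] * expm1(g * t) / g
      exp(-cumhaz)
    },
    loglogistic = 1 / (1 + (t / v[[1]])^v[[2]]))
}

#' Hazard function h(t)
#'
#' Errors when the hazard is infinite at `t = 0` (Weibull with shape `< 1`,
#' log-logistic with shape `< 1`).
#'
#' @inheritParams surv_prob
#' @return hazard rates per month.
#' @export
haz_rate <- function(theta, t) {
  stopifnot(inherits(theta, "surv_param"))
  if (any(t < 0)) stop("negative time in haz_rate()", call. = FALSE)
  v <- theta$values
  fam <- theta$family$name
  if (any(t == 0)) {
    shp <- if (fam %in% c("weibull", "loglogistic")) v[[2]] else 1
    if (shp < 1) {
      stop("infinite hazard at t = 0 for ", fam, " with shape ", shp,
           " < 1", call. = FALSE)
    }
  }
  switch(fam,
    exponential = rep_len(v[[1]], length(t)),
    weibull     = v[[1]] * v[[2]] * t^(v[[2]] - 1),
    gompertz    = v[[1]] * exp(v[[2]] * t),
    loglogistic = {
      x <- (t / v[[1]])^v[[2]]
      (v[[2]] / v[[1]]) * (t / v[[1]])^(v[[2]] - 1) / (1 + x)
    })
}

#' Conditional probability of death within an interval
#'
#' `p = 1 - S(t1)/S(t0)`, the probability that a patient alive at `t0` dies
#' before `t1`.  This is the success probability of the binomial likelihood
#' on monthly interval counts.
#'
#' @param theta a [surv_param()].
#' @param t0,t1 interval bounds in months, `0 <= t0 < t1` (vectorized).
#' @export
interval_death_prob <- function(theta, t0, t1) {
  if (any(t0 < 0) || any(t1 <= t0)) {
    stop("need 0 <= t0 < t1 in interval_death_prob()", call. = FALSE)
  }
  s0 <- surv_prob(theta, t0)
  if (any(s0 <= 0)) stop("S(t0) = 0: no one at risk under the model", call. = FALSE)
  p <- 1 - surv_prob(theta, t1) / s0
  pmin(pmax(p, 0), 1)
}

#' Additive treatment effect on the transformed scale
#'
#' Shifts every transformed parameter of `mu` by `delta` and back-transforms.
#' For the exponential family the single delta is the log hazard ratio.
#'
#' @param mu baseline [surv_param()].
#' @param delta numeric effect vector on the transformed scale, length
#'   `mu$family$dim` (a scalar 0 is recycled).
#' @return a `surv_param` of the same family.
#' @export
apply_effect <- function(mu, delta) {
  stopifnot(inherits(mu, "surv_param"))
  if (inherits(delta, "surv_param")) stop("delta must be a numeric effect vector",
                                          call. = FALSE)
  delta <- as.numeric(delta)
  if (length(delta) == 1L) delta <- rep(delta, mu$family$dim)
  if (length(delta) != mu$family$dim) {
    stop("effect dimension ", length(delta), " does not match family '",
         mu$family$name, "' (dim ", mu$family$dim, ")", call. = FALSE)
  }
  if (any(!is.finite(delta))) stop("non-finite effect", call. = FALSE)
  from_transformed(mu$family, to_transformed(mu) + delta)
}

#' Hazard ratio between two parameter vectors
#'
#' @param theta_a,theta_b [surv_param()] objects of the same family.
#' @param t time in months (vectorized).
#' @export
hazard_ratio <- function(theta_a, theta_b, t) {
  if (!identical(theta_a$family$name, theta_b$family$name)) {
    stop("hazard_ratio() requires a common family", call. = FALSE)
  }
  hb <- haz_rate(theta_b, t)
  if (any(hb == 0)) stop("zero denominator hazard in hazard_ratio()", call. = FALSE)
  haz_rate(theta_a, t) / hb
}

#' Inverse-CDF sampling of death times
#'
#' @param theta a [surv_param()].
#' @param n number of draws; uses the current RNG state.
#' @return death times in months; `Inf` where the distribution has
#'   defective mass (Gompertz with negative shape).
#' @keywords internal
r_surv_time <- function(theta, n) {
  v <- theta$values
  u <- stats::runif(n)
  switch(theta$family$name,
    exponential = -log(u) / v[[1]],
    weibull     = (-log(u) / v[[1]])^(1 / v[[2]]),
    gompertz    = {
      g <- v[[2]]
      if (abs(g) < 1e-12) -log(u) / v[[1]]
      else {
        arg <- 1 + g * (-log(u)) / v[[1]]
        out <- rep(Inf, n)           # defective tail when shape < 0
        ok <- arg > 0
        out[ok] <- log(arg[ok]) / g
        out
      }
    },
    loglogistic = v[[1]] * (1 / u - 1)^(1 / v[[2]]))
}
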