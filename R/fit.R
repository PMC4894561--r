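#' Posterior sampling, convergence diagnostics and DIC
#'
#' The sampler is an adaptive random-walk Metropolis scheme (global scale
#' tuned toward a 0.234 acceptance rate, proposal covariance learned from
#' the chain history during burn-in).  The contract is the posterior, not
#' the algorithm: any correct MCMC scheme would do; this one needs no
#' external engine and handles the 4-8 dimensional fixed-effect models
#' involved here comfortably.
#'
#' @name nma-fitting
NULL

# posterior mode and curvature: anchors the chains and the proposal shape
map_estimate <- function(model) {
  init <- nma_init(model)
  neg <- function(p) -nma_logpost(model, p)
  opt <- stats::optim(init, neg, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-10))
  cov0 <- tryCatch({
    cc <- solve(opt$hessian)
    if (all(is.finite(cc)) && all(diag(cc) > 0)) cc else NULL
  }, error = function(e) NULL)
  if (is.null(cov0)) cov0 <- diag(0.05, model$npar)
  list(mode = opt$par, cov = cov0)
}

# one adaptive Metropolis chain
run_chain <- function(model, iterations, burn_in, init, thin = 1,
                      cov0 = diag(0.1, model$npar)) {
  npar <- model$npar
  par <- init
  lp <- nma_logpost(model, par)
  keep <- floor((iterations - burn_in) / thin)
  out <- matrix(NA_real_, keep, npar)
  log_scale <- log(2.38^2 / npar)
  mean_vec <- par
  cov_mat <- cov0
  emp_cov <- matrix(0, npar, npar)
  chol_prop <- chol(exp(log_scale) * (cov_mat + diag(1e-10, npar)))
  n_seen <- 1
  kept <- 0L
  for (it in seq_len(iterations)) {
    prop <- par + drop(stats::rnorm(npar) %*% chol_prop)
    lp_prop <- nma_logpost(model, prop)
    acc <- is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp
    if (acc) { par <- prop; lp <- lp_prop }
    if (it <= burn_in) {
      # Robbins-Monro scale adaptation + running covariance; the empirical
      # covariance replaces cov0 only once enough history has accumulated
      rate <- if (acc) 1 else 0
      log_scale <- log_scale + (rate - 0.234) / sqrt(it)
      n_seen <- n_seen + 1
      dlt <- par - mean_vec
      mean_vec <- mean_vec + dlt / n_seen
      emp_cov <- if (n_seen == 2) tcrossprod(dlt) / 2
                 else emp_cov * (n_seen - 2) / (n_seen - 1) +
                   tcrossprod(dlt) / n_seen
      if (it %% 25 == 0 || it == burn_in) {
        base_cov <- if (n_seen > 20 * npar) emp_cov else cov_mat
        cc <- exp(log_scale) * (base_cov + diag(1e-8, npar))
        ch <- tryCatch(chol(cc), error = function(e) NULL)
        if (!is.null(ch)) chol_prop <- ch
      }
    } else if ((it - burn_in) %% thin == 0) {
      kept <- kept + 1L
      out[kept, ] <- par
    }
  }
  out[seq_len(kept), , drop = FALSE]
}

#' Fit a network model by MCMC
#'
#' @param model an [build_model()] result.
#' @param chains number of chains (`>= 2` for [psrf()]).
#' @param iterations total iterations per chain.
#' @param burn_in adaptation/warm-up iterations discarded from the output.
#' @param seed integer seed; mandatory for reproducibility.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param init_sd chain starting points are the posterior mode jittered by
#'   `init_sd` posterior standard deviations (overdispersed starts make the
#'   PSRF diagnostic meaningful).
#' @param max_retries re-draws of the initial point if the posterior is
#'   non-finite there.
#' @return object of class `nma_draws`: `draws` is an array
#'   `iterations x parameters x chains` on the transformed scale.
#' @export
nma_fit <- function(model, chains = 3, iterations = 20000,
                    burn_in = 10000, seed, thin = 1, init_sd = 2,
                    max_retries = 50) {
  stopifnot(inherits(model, "nma_model"), chains >= 1,
            iterations > burn_in)
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  map <- map_estimate(model)
  scale0 <- sqrt(pmax(diag(map$cov), 1e-8))
  with_seed(seed, {
    chain_list <- vector("list", chains)
    for (ch in seq_len(chains)) {
      init <- NULL
      for (try in seq_len(max_retries)) {
        cand <- map$mode + stats::rnorm(model$npar, 0, init_sd) * scale0
        if (is.finite(nma_logpost(model, cand))) { init <- cand; break }
      }
      if (is.null(init)) {
        stop("could not find a finite-posterior initial point after ",
             max_retries, " tries", call. = FALSE)
      }
      chain_list[[ch]] <- run_chain(model, iterations, burn_in, init, thin,
                                    cov0 = map$cov)
    }
    n_kept <- min(vapply(chain_list, nrow, integer(1)))
    draws <- array(NA_real_, c(n_kept, model$npar, chains),
                   dimnames = list(NULL, model$par_names, NULL))
    for (ch in seq_len(chains)) draws[, , ch] <- chain_list[[ch]][seq_len(n_kept), ]
    structure(list(draws = draws, model = model,
                   meta = list(seed = seed, chains = chains,
                               iterations = iterations, burn_in = burn_in,
                               thin = thin)),
              class = "nma_draws")
  })
}

#' @export
print.nma_draws <- function(x, ...) {
  cat("<nma_draws> family:", x$model$family$name, "|",
      dim(x$draws)[3], "chains x", dim(x$draws)[1], "draws x",
      dim(x$draws)[2], "parameters\n")
  invisible(x)
}

# all chains stacked: matrix (chains * iterations) x parameters
stack_draws <- function(draws) {
  d <- draws$draws
  out <- do.call(rbind, lapply(seq_len(dim(d)[3]), function(ch) d[, , ch]))
  colnames(out) <- draws$model$par_names
  out
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-split) PSRF per parameter:
#' `sqrt(((n - 1)/n * W + B/n) / W)` with `W` the mean within-chain
#' variance and `B/n` the variance of the chain means.
#'
#' @param draws an [nma_fit()] result (or a plain
#'   iterations x parameters x chains array).
#' @return named numeric vector, one value per parameter.
#' @export
psrf <- function(draws) {
  d <- if (inherits(draws, "nma_draws")) draws$draws else draws
  stopifnot(length(dim(d)) == 3)
  m <- dim(d)[3]
  if (m < 2) stop("psrf() needs at least 2 chains", call. = FALSE)
  n <- dim(d)[1]
  out <- vapply(seq_len(dim(d)[2]), function(j) {
    x <- d[, j, ]
    W <- mean(apply(x, 2, stats::var))
    B_over_n <- stats::var(colMeans(x))
    if (W <= 0) return(if (B_over_n <= 0) 1 else Inf)
    sqrt(((n - 1) / n * W + B_over_n) / W)
  }, numeric(1))
  names(out) <- dimnames(d)[[2]]
  out
}

#' Deviance information criterion
#'
#' `D(theta) = -2 log L` (binomial likelihood including the combinatorial
#' constant); `pD = mean(D) - D(posterior mean)` with the posterior mean
#' taken on the transformed scale; `DIC = mean(D) + pD`.
#'
#' @param draws an [nma_fit()] result.
#' @param model optional model override (defaults to the fitted one).
#' @return list with `dic`, `pD`, `mean_deviance`.
#' @export
nma_dic <- function(draws, model = draws$model) {
  stacked <- stack_draws(draws)
  dev <- -2 * apply(stacked, 1, function(p) nma_loglik(model, p))
  dbar <- mean(dev)
  dhat <- -2 * nma_loglik(model, colMeans(stacked))
  pD <- dbar - dhat
  list(dic = dbar + pD, pD = pD, mean_deviance = dbar)
}

#' Convergence-and-fit diagnostics bundle
#'
#' @inheritParams nma_dic
#' @return list with `psrf` (per parameter), `max_psrf`, `dic`, `pD`,
#'   `mean_deviance`.
#' @export
nma_diagnostics <- function(draws, model = draws$model) {
  r <- psrf(draws)
  d <- nma_dic(draws, model)
  list(psrf = as.list(r), max_psrf = max(r), dic = d$dic, pD = d$pD,
       mean_deviance = d$mean_deviance)
}
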