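# shared fixtures: built in code, cached per test run so expensive fits
# are reused across test files (testthat sources helpers once per run)

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# stacked monthly interval counts for the default scenario at n per arm
sim_network_data <- function(seed, n_per_arm = 400, horizon = 24) {
  arms <- simulate_scenario(default_scenario(n_per_arm = n_per_arm),
                            seed = seed, horizon = horizon)
  do.call(rbind, lapply(arms, function(a)
    bin_monthly(a$ipd, a$study, a$treatment, horizon = horizon)))
}

# quick MCMC settings: reduced from the 20000/10000 production default to
# keep the suite inside its time budget; adequate for 4-8 parameter models
quick_fit <- function(model, seed, iterations = 3000, burn_in = 1500) {
  nma_fit(model, chains = 3, iterations = iterations, burn_in = burn_in,
          seed = seed)
}

# moderately long fit shared by the tests that need converged chains
shared_ll_fit <- function() {
  cached("ll_fit", {
    dat <- sim_network_data(seed = 7)
    m <- build_model(dat, "loglogistic")
    nma_fit(m, chains = 3, iterations = 6000, burn_in = 3000, seed = 11)
  })
}

shared_exp_fit <- function() {
  cached("exp_fit", {
    dat <- sim_network_data(seed = 7)
    m <- build_model(dat, "exponential")
    nma_fit(m, chains = 3, iterations = 4000, burn_in = 2000, seed = 11)
  })
}

# hand-built draws object (e.g. degenerate posteriors) for summary tests
manual_draws <- function(model, stacked_matrix, chains = 2) {
  n <- nrow(stacked_matrix) / chains
  d <- array(NA_real_, c(n, model$npar, chains),
             dimnames = list(NULL, model$par_names, NULL))
  for (ch in seq_len(chains)) d[, , ch] <- stacked_matrix[(ch - 1) * n + seq_len(n), ]
  structure(list(draws = d, model = model,
                 meta = list(seed = NA, chains = chains)),
            class = "nma_draws")
}
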