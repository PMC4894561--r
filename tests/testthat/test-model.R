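# network model construction, likelihood, MCMC, PSRF and DIC

test_that("model structure: parameter counts and network checks", {
  dat <- sim_network_data(seed = 3, n_per_arm = 100)
  for (fam in c("exponential", "weibull", "gompertz", "loglogistic")) {
    m <- build_model(dat, fam)
    dim <- surv_family(fam)$dim
    # 2 study baselines + 2 non-reference effects, each of family dim
    expect_equal(m$npar, 4 * dim)
    expect_equal(m$ref_treatment, "everolimus")
  }
  # disconnected network: two studies with no shared treatment
  bad <- dat
  bad$treatment[bad$study == "choueiri_like" &
                  bad$treatment == "everolimus"] <- "placebo"
  expect_error(build_model(bad, "exponential"), "disconnected")
  expect_error(build_model(dat[dat$treatment == "everolimus", ], "exponential"),
               "two arms")
})

test_that("log-likelihood equals a brute-force binomial summation", {
  dat <- sim_network_data(seed = 3, n_per_arm = 100)
  for (fam in c("exponential", "weibull", "gompertz", "loglogistic")) {
    m <- build_model(dat, fam)
    set.seed(17)
    par <- nmasurv:::nma_init(m) + rnorm(m$npar, 0, 0.2)
    # independent oracle: loop rows, compose arm parameters explicitly
    names(par) <- m$par_names
    ll <- 0
    for (i in seq_len(nrow(m$rows))) {
      r <- m$rows[i, ]
      dim <- m$dim
      mu <- par[paste0("mu[", r$study, ",", m$family$par_names, "]")]
      dvec <- function(trt) {
        if (trt == m$ref_treatment) rep(0, dim)
        else par[paste0("d[", trt, ",", m$family$par_names, "]")]
      }
      eta <- mu + dvec(r$treatment) - dvec(m$study_ref[[r$study]])
      theta <- from_transformed(fam, unname(eta))
      p <- interval_death_prob(theta, r$interval_start, r$interval_start + 1)
      ll <- ll + dbinom(r$deaths, m$size[i], p, log = TRUE)
    }
    expect_equal(nma_loglik(m, unname(par)), ll, tolerance = 1e-8)
  }
})

test_that("reference-arm rows respond only to the study baseline", {
  dat <- sim_network_data(seed = 3, n_per_arm = 100)
  m <- build_model(dat, "weibull")
  ref_only <- dat[dat$treatment == "everolimus", ]
  p0 <- nmasurv:::nma_init(m)
  p1 <- p0
  p1[5:8] <- p1[5:8] + 0.3          # effect parameters only
  # likelihood change equals the change on non-reference rows alone
  m_nonref <- m
  keep <- m$rows$treatment != "everolimus"
  for (f in c("rows", "size", "study_idx", "trt_idx", "ref_trt_idx",
              "lchoose_const")) {
    m_nonref[[f]] <- if (is.data.frame(m[[f]])) m[[f]][keep, ] else m[[f]][keep]
  }
  expect_equal(nma_loglik(m, p1) - nma_loglik(m, p0),
               nma_loglik(m_nonref, p1) - nma_loglik(m_nonref, p0),
               tolerance = 1e-8)
})

test_that("single-study exponential posterior matches the closed-form MLE", {
  arm_e <- list(treatment = "ctrl", n = 500,
                theta = surv_param("exponential", 0.04))
  arm_t <- list(treatment = "trt", n = 500,
                theta = surv_param("exponential", 0.03))
  ipd_e <- simulate_arm(arm_e, censor_rate = 0.005, max_followup = 40,
                        accrual_window = 5, seed = 31)
  ipd_t <- simulate_arm(arm_t, censor_rate = 0.005, max_followup = 40,
                        accrual_window = 5, seed = 32)
  dat <- rbind(bin_monthly(ipd_e, "s1", "ctrl"),
               bin_monthly(ipd_t, "s1", "trt"))
  m <- build_model(dat, "exponential", prior_normal(10))
  dr <- quick_fit(m, seed = 101)
  st <- nmasurv:::stack_draws(dr)
  ctrl_rows <- m$rows$treatment == "ctrl"
  mle <- sum(m$rows$deaths[ctrl_rows]) / sum(m$size[ctrl_rows])
  post_rate <- mean(exp(st[, "mu[s1,rate]"]))
  # interval-count MLE uses whole person-months: agree within 5%
  expect_lt(abs(post_rate - -log(1 - mle)) / -log(1 - mle), 0.05)
})

test_that("two identical arms: effect posterior centred at zero", {
  arm <- list(treatment = "a", n = 400,
              theta = surv_param("exponential", 0.04))
  ipd <- simulate_arm(arm, censor_rate = 0, max_followup = 30,
                      accrual_window = 5, seed = 55)
  dat <- rbind(bin_monthly(ipd, "s1", "a"),
               {
                 b <- bin_monthly(ipd, "s1", "b")
                 b
               })
  m <- build_model(dat, "exponential", ref_treatment = "a")
  dr <- quick_fit(m, seed = 77)
  st <- nmasurv:::stack_draws(dr)
  ci <- quantile(st[, "d[b,rate]"], c(0.025, 0.975))
  expect_lt(ci[1], 0)
  expect_gt(ci[2], 0)
})

test_that("fit is reproducible given a seed and requires one", {
  dat <- sim_network_data(seed = 3, n_per_arm = 100)
  m <- build_model(dat, "exponential")
  d1 <- nma_fit(m, chains = 2, iterations = 400, burn_in = 200, seed = 9)
  d2 <- nma_fit(m, chains = 2, iterations = 400, burn_in = 200, seed = 9)
  expect_identical(d1$draws, d2$draws)
  expect_error(nma_fit(m, chains = 2, iterations = 400, burn_in = 200),
               "seed")
})

test_that("psrf: copies, stationary chains, divergent chains", {
  dat <- sim_network_data(seed = 3, n_per_arm = 100)
  m <- build_model(dat, "exponential")
  n <- 500
  one <- matrix(rnorm(n * m$npar), n, m$npar)
  same <- manual_draws(m, rbind(one, one), chains = 2)
  expect_true(all(abs(psrf(same) - 1) < 0.002))
  set.seed(12)
  stat <- manual_draws(m, matrix(rnorm(2 * n * m$npar), 2 * n, m$npar),
                       chains = 2)
  expect_true(all(psrf(stat) <= 1.01))
  apart <- manual_draws(m, rbind(one, one + 100), chains = 2)
  expect_true(all(psrf(apart) > 10))
  expect_error(psrf(manual_draws(m, one, chains = 1)), "2 chains")
})

test_that("DIC: degenerate posterior and replicate stability", {
  dat <- sim_network_data(seed = 3, n_per_arm = 100)
  m <- build_model(dat, "exponential")
  theta_hat <- nmasurv:::nma_init(m)
  deg <- manual_draws(m, matrix(rep(theta_hat, each = 40), 40, m$npar),
                      chains = 2)
  d <- nma_dic(deg)
  expect_equal(d$pD, 0, tolerance = 1e-8)
  expect_equal(d$dic, -2 * nma_loglik(m, theta_hat), tolerance = 1e-8)
  # independent seeded runs agree within Monte-Carlo error
  r1 <- nma_dic(nma_fit(m, chains = 3, iterations = 6000, burn_in = 3000,
                        seed = 21))
  r2 <- nma_dic(nma_fit(m, chains = 3, iterations = 6000, burn_in = 3000,
                        seed = 22))
  expect_lt(abs(r1$dic - r2$dic), 2)
  expect_gt(r1$pD, 0)
})

test_that("parameter recovery on one paper-like replicate", {
  dr <- shared_ll_fit()
  st <- nmasurv:::stack_draws(dr)
  truth <- default_scenario()$truth
  for (trt in c("nivolumab", "cabozantinib")) {
    for (j in 1:2) {
      col <- paste0("d[", trt, ",", c("scale", "shape")[j], "]")
      ci <- quantile(st[, col], c(0.025, 0.975))
      expect_gt(truth$delta[[trt]][j], ci[1])
      expect_lt(truth$delta[[trt]][j], ci[2])
    }
  }
})
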