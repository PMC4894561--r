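# Bucher comparison, HR series, adjusted survival, probability-best

test_that("Bucher indirect comparison reproduces the published contrast", {
  res <- bucher_indirect(0.73, c(0.57, 0.93), 0.985,
                         0.67, c(0.51, 0.89), 0.95)
  expect_equal(res$hr, 0.73 / 0.67, tolerance = 1e-12)
  expect_equal(round(res$hr, 2), 1.09)
  expect_lt(abs(res$ci95[1] - 0.77), 0.01)
  expect_lt(abs(res$ci95[2] - 1.54), 0.01)
  # combined log-scale SE by direct arithmetic
  se_a <- (log(0.93) - log(0.57)) / (2 * qnorm(1 - 0.015 / 2))
  se_b <- (log(0.89) - log(0.51)) / (2 * qnorm(0.975))
  expect_equal(res$log_se, sqrt(se_a^2 + se_b^2), tolerance = 1e-12)
  expect_equal(round(res$log_se, 3), 0.174)
})

test_that("Bucher identity case and input validation", {
  res <- bucher_indirect(0.8, c(0.6, 1.05), 0.95, 0.8, c(0.6, 1.05), 0.95)
  expect_equal(res$hr, 1)
  expect_equal(log(res$ci95[2]), -log(res$ci95[1]), tolerance = 1e-12)
  expect_error(bucher_indirect(0.8, c(1.05, 0.6), 0.95,
                               0.8, c(0.6, 1.05), 0.95), "lower, upper")
})

test_that("odds_best arithmetic", {
  expect_equal(odds_best(0.5), 1)
  expect_equal(round(odds_best(0.595), 2), 1.47)
  expect_equal(odds_best(0.68), 2.125, tolerance = 1e-12)  # prints as 2.12
  expect_error(odds_best(1), "p = 1")
})

test_that("exponential HR series is constant; summaries are nested", {
  dr <- shared_exp_fit()
  hs <- hr_series(dr, c("nivolumab", "cabozantinib"), grid = 1:24)
  expect_equal(hs$median, rep(hs$median[1], 24))
  expect_equal(hs$mean, rep(hs$mean[1], 24))
  expect_true(all(hs$lo95 <= hs$lo50 & hs$hi50 <= hs$hi95))
  expect_true(all(hs$lo50 <= hs$median & hs$median <= hs$hi50))
  expect_true(all(hs$lo95 > 0))
})

test_that("per-draw transitivity: pair series equals ratio of vs-reference", {
  dr <- shared_ll_fit()
  eta_n <- nmasurv:::draw_eta(dr, "motzer_like", "nivolumab")
  eta_c <- nmasurv:::draw_eta(dr, "motzer_like", "cabozantinib")
  eta_e <- nmasurv:::draw_eta(dr, "motzer_like", "everolimus")
  for (t in c(3, 12, 24)) {
    hr_nc <- nmasurv:::haz_eta("loglogistic", eta_n, t) /
      nmasurv:::haz_eta("loglogistic", eta_c, t)
    hr_ne <- nmasurv:::haz_eta("loglogistic", eta_n, t) /
      nmasurv:::haz_eta("loglogistic", eta_e, t)
    hr_ce <- nmasurv:::haz_eta("loglogistic", eta_c, t) /
      nmasurv:::haz_eta("loglogistic", eta_e, t)
    expect_equal(hr_nc, hr_ne / hr_ce, tolerance = 1e-12)
  }
})

test_that("time-varying HR declines and crosses for the log-logistic fit", {
  dr <- shared_ll_fit()
  hs <- hr_series(dr, c("nivolumab", "cabozantinib"), grid = 1:24)
  expect_gt(hs$median[1], 1)          # cabozantinib favoured early
  expect_lt(hs$median[24], 1)         # nivolumab favoured late
  expect_true(all(diff(hs$median) < 0))
})

test_that("adjusted survival: axioms and reference-treatment identity", {
  dr <- shared_ll_fit()
  surv <- adjusted_survival(dr, reference_study = "motzer_like",
                            grid = 0:24)
  for (trt in unique(surv$treatment)) {
    s <- surv[surv$treatment == trt, ]
    expect_equal(s$mean[s$time == 0], 1)
    expect_true(all(diff(s$median) <= 0))
    expect_true(all(s$lo95 <= s$median & s$median <= s$hi95))
  }
  # the study's own baseline arm equals the baseline posterior survival
  st <- nmasurv:::stack_draws(dr)
  s12 <- 1 / (1 + (12 / exp(st[, "mu[motzer_like,scale]"]))^
                exp(st[, "mu[motzer_like,shape]"]))
  ref_row <- surv[surv$treatment == "everolimus" & surv$time == 12, ]
  expect_equal(ref_row$mean, mean(s12), tolerance = 1e-12)
  expect_error(adjusted_survival(dr, reference_study = "nope"), "not in")
})

test_that("prob_best: partition of draws, tie splitting, degenerate case", {
  dr <- shared_ll_fit()
  pb <- prob_best(dr, grid = 1:24)
  probs <- as.matrix(pb[, -1])
  expect_equal(unname(rowSums(probs)), rep(1, 24), tolerance = 1e-12)
  expect_true(all(probs >= 0 & probs <= 1))
  # when both effect posteriors concentrate on strong benefit the
  # reference is (near) never best
  m <- dr$model
  set.seed(9)
  strong <- matrix(rep(nmasurv:::nma_init(m), each = 400), 400, m$npar)
  colnames(strong) <- m$par_names
  for (trt in c("nivolumab", "cabozantinib")) {
    strong[, paste0("d[", trt, ",scale]")] <- rnorm(400, 0.5, 0.1)
    strong[, paste0("d[", trt, ",shape]")] <- rnorm(400, 0, 0.05)
  }
  strong <- strong + 0  # plain matrix
  pbs <- prob_best(manual_draws(m, strong, chains = 2), grid = 1:24)
  expect_true(all(pbs[, "everolimus"] < 0.02))
  # degenerate posterior: one treatment uniformly superior
  m <- dr$model
  base <- nmasurv:::nma_init(m)
  names(base) <- m$par_names
  base["d[nivolumab,scale]"] <- 1     # large scale advantage
  deg <- manual_draws(m, matrix(rep(unname(base), each = 20), 20, m$npar),
                      chains = 2)
  pb2 <- prob_best(deg, grid = c(6, 12))
  expect_equal(unname(pb2[, "nivolumab"]), c(1, 1))
  # exact ties split equally
  tie <- base
  tie[5:8] <- 0                        # all effects zero: three-way tie
  degt <- manual_draws(m, matrix(rep(unname(tie), each = 20), 20, m$npar),
                       chains = 2)
  pb3 <- prob_best(degt, grid = 6)
  expect_equal(unname(unlist(pb3[, -1])), rep(1 / 3, 3), tolerance = 1e-12)
})

test_that("exponential prob_best is time-constant", {
  dr <- shared_exp_fit()
  pb <- prob_best(dr, grid = c(1, 6, 12, 24))
  for (j in 2:4) expect_equal(unname(unlist(pb[j, -1])),
                              unname(unlist(pb[1, -1])), tolerance = 1e-12)
})

test_that("hr_table subsets at the reporting cadence", {
  dr <- shared_exp_fit()
  hs <- hr_series(dr, c("nivolumab", "cabozantinib"), grid = 1:24)
  tab <- hr_table(hs)
  expect_equal(tab$time, seq(3, 24, by = 3))
})
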