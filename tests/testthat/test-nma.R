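test_that("a single vague-prior datum is reproduced by the posterior", {
  ds <- make_contrasts("s1", "B", "A", -0.5, 0.1)
  fit <- fit_nma(ds, nma_config(chains = 2, iterations = 6000,
                                burn_in = 1000, thin = 1, seed = 2,
                                effects = "fixed", prior_sd_d = 15))
  expect_lt(abs(mean(fit$d[, "B"]) + 0.5), 0.01)
  expect_lt(abs(sd(fit$d[, "B"]) - 0.1), 0.01)
  expect_true(all(fit$d[, "A"] == 0))
})

test_that("indirect chains add means and variances", {
  ds <- make_contrasts(c("s1", "s2"), c("B", "C"), c("A", "B"),
                       c(0.3, 0.2), 0.1)
  fit <- fit_nma(ds, nma_config(chains = 2, iterations = 6000,
                                burn_in = 1000, thin = 1, seed = 3,
                                effects = "fixed"), reference = "A")
  expect_lt(abs(mean(fit$d[, "C"]) - 0.5), 0.01)
  expect_lt(abs(sd(fit$d[, "C"]) - sqrt(0.02)), 0.01)
})

test_that("fixed-effect NMA matches the independent GLS oracle", {
  for (seed in c(11, 12)) {
    truth <- sim_truth(n_treat = 4, n_trials = 6, sigma = 0, seed = seed)
    sim <- simulate_contrast_network(truth)
    fit <- fit_nma(sim$dataset, cfg_fast(seed = seed), reference = "Pla")
    oracle <- gls_solve(sim$dataset, "Pla", prior_sd = fit$prior_sd_d)
    est <- colMeans(fit$d)[names(oracle)]
    expect_lt(max(abs(est - oracle)), 0.02)
  }
})

test_that("posterior contrasts are invariant to the reference treatment", {
  sim <- simulate_contrast_network(sim_truth(n_treat = 4, n_trials = 8,
                                             sigma = 0.1, seed = 21))
  f1 <- fit_nma(sim$dataset, cfg_fast(seed = 4), reference = "Pla")
  f2 <- fit_nma(sim$dataset, cfg_fast(seed = 5), reference = "Sor")
  for (t2 in c("Sor", "D1", "D2")) {
    m1 <- median(f1$d[, t2] - f1$d[, "Pla"])
    m2 <- median(f2$d[, t2] - f2$d[, "Pla"])
    expect_lt(abs(m1 - m2), 0.012)
  }
})

test_that("fits are bit-reproducible under a fixed seed", {
  ds <- simulate_contrast_network(sim_truth(seed = 8))$dataset
  f1 <- fit_nma(ds, cfg_mini(seed = 7, effects = "random"))
  f2 <- fit_nma(ds, cfg_mini(seed = 7, effects = "random"))
  expect_identical(f1$d, f2$d)
  expect_identical(f1$sigma, f2$sigma)
  f3 <- fit_nma(ds, cfg_mini(seed = 8, effects = "random"))
  expect_false(identical(f1$d, f3$d))
})

test_that("heterogeneity posterior concentrates near zero for homogeneous data", {
  meds <- vapply(1:5, function(r) {
    ds <- simulate_contrast_network(sim_truth(sigma = 0, seed = 40 + r,
                                              events_range = 200))$dataset
    fit <- fit_nma(ds, nma_config(chains = 2, iterations = 8000,
                                  burn_in = 2000, thin = 1, seed = r,
                                  effects = "random"))
    median(fit$sigma)
  }, 0)
  expect_lt(median(meds), 0.15)
})

test_that("residual deviance is calibrated and DIC penalizes the random model on homogeneous data", {
  ratio <- dic_f <- dic_r <- pd_f <- pd_r <- numeric(4)
  for (r in 1:4) {
    ds <- simulate_contrast_network(sim_truth(sigma = 0, seed = 60 + r))$dataset
    ff <- fit_nma(ds, cfg_fast(seed = r, effects = "fixed"))
    fr <- fit_nma(ds, cfg_fast(seed = r, effects = "random"))
    ratio[r] <- ff$Dbar / ff$n_data
    dic_f[r] <- ff$DIC; dic_r[r] <- fr$DIC
    pd_f[r] <- ff$pD; pd_r[r] <- fr$pD
  }
  expect_gt(mean(ratio), 0.8)
  expect_lt(mean(ratio), 1.2)
  expect_true(all(pd_f < pd_r))
  expect_lt(mean(dic_r - dic_f), 3)
})

test_that("the UME structure saturates a one-study-per-comparison star", {
  ds <- make_contrasts(paste0("s", 1:4), c("B", "C", "D", "E"), "A",
                       c(0.2, -0.3, 0.5, 0), 0.1)
  fit <- fit_nma(ds, nma_config(chains = 2, iterations = 4000,
                                burn_in = 1000, thin = 1, seed = 9,
                                effects = "fixed", structure = "ume"))
  expect_equal(fit$Dbar / fit$n_data, 1, tolerance = 0.3)
  expect_equal(fit$DIC, fit$Dbar + fit$pD)
})

test_that("league tables are reciprocal and reproduce a 3-draw enumeration", {
  stub <- structure(list(
    d = cbind(A = c(0, 0, 0), B = c(0.1, 0.2, 0.3)),
    treatments = c("A", "B")), class = "nma_fit")
  lt <- league_table(stub)
  expect_equal(lt$median["A", "B"], exp(0.2))
  expect_equal(lt$median["B", "A"], exp(-0.2))
  # degenerate fit: all off-diagonal cells exactly 1
  stub0 <- structure(list(d = cbind(A = rep(0, 5), B = rep(0, 5)),
                          treatments = c("A", "B")), class = "nma_fit")
  expect_equal(league_table(stub0)$median["A", "B"], 1)
  # reciprocity at machine precision on a real fit
  sim <- simulate_contrast_network(sim_truth(seed = 13))
  fit <- fit_nma(sim$dataset, cfg_mini(seed = 6))
  m <- league_table(fit)$median
  for (r in seq_len(nrow(m))) for (cl in seq_len(ncol(m)))
    if (r != cl) expect_equal(m[r, cl] * m[cl, r], 1, tolerance = 1e-12)
  expect_error(league_table(fit, order = c("Pla", "Nope")), "unknown")
  ll <- league_long(league_table(fit))
  expect_equal(nrow(ll), length(fit$treatments) * (length(fit$treatments) - 1))
})

test_that("convergence diagnostics behave on known chains", {
  set.seed(123)
  iid <- list(matrix(rnorm(5000), ncol = 1), matrix(rnorm(5000), ncol = 1))
  dg <- convergence_diagnostics(iid)
  expect_lt(dg$psrf, 1.01)
  expect_lt(abs(dg$autocorr[1, 1]), 0.05)
  expect_gt(dg$ess, 5000)
  # two constant chains at different values: flagged as divergent
  const <- list(matrix(1, 100, 1), matrix(2, 100, 1))
  expect_gt(convergence_diagnostics(const)$psrf, 10)
  # strongly autocorrelated AR(1): ESS collapses
  ar <- as.vector(stats::arima.sim(list(ar = 0.9), 5000))
  dga <- convergence_diagnostics(list(matrix(ar, ncol = 1)))
  expect_lt(dga$ess / 5000, 0.15)
})

test_that("binomial arm data recover a known odds ratio", {
  truth <- sim_truth(n_treat = 3, n_trials = 4, sigma = 0,
                     d = c(0, -0.3, log(2)), n_range = 4000, seed = 17)
  sim <- simulate_binary_network(truth, p_baseline = 0.3)
  fit <- fit_nma(sim$dataset, cfg_fast(seed = 18, effects = "fixed"),
                 reference = "Pla")
  expect_lt(abs(median(fit$d[, "D1"]) - log(2)), 0.15)
  expect_lt(abs(median(fit$d[, "Sor"]) + 0.3), 0.15)
  # random effects on the same data stay close
  fr <- fit_nma(sim$dataset, cfg_fast(seed = 19, effects = "random"),
                reference = "Pla")
  expect_lt(abs(median(fr$d[, "D1"]) - log(2)), 0.2)
})

test_that("configuration and input validation catch misuse", {
  expect_error(nma_config(chains = 1), "2 chains")
  expect_error(nma_config(burn_in = 2000, iterations = 1000), "burn_in")
  expect_error(nma_config(thin = 0), "thin")
  expect_error(nma_config(sigma_upper = -1), "sigma_upper")
  split_ds <- make_contrasts(c("s1", "s2"), c("B", "D"), c("A", "C"), 0, 0.1)
  expect_error(fit_nma(split_ds, cfg_mini()), "disconnected")
  one <- make_contrasts("s1", "B", "A", 0, 0.1)
  expect_error(fit_nma(one, cfg_mini(effects = "random")), "at least 2")
})
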