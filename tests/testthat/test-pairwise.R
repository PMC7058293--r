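# the two pivotal sorafenib-vs-placebo OS trials, reconstructed from their
# reported CIs, are the worked example used throughout
sor_pla <- function() {
  e1 <- effect_from_ci(0.69, 0.55, 0.87)
  e2 <- effect_from_ci(0.68, 0.50, 0.93)
  data.frame(treatment = "Sor", reference = "Pla",
             estimate = c(e1$estimate, e2$estimate),
             std_err = c(e1$std_err, e2$std_err))
}

test_that("inverse-variance fixed-effect pooling matches the hand computation", {
  res <- pool_fixed_iv(sor_pla())
  expect_equal(res$estimate, -0.37623, tolerance = 1e-4)
  expect_equal(exp(res$estimate), 0.6864, tolerance = 1e-3)
  expect_equal(exp(c(res$ci_lower, res$ci_upper)), c(0.5708, 0.8255),
               tolerance = 1e-3)
  # single effect passes through unchanged
  one <- pool_fixed_iv(data.frame(estimate = -0.5, std_err = 0.2))
  expect_equal(one$estimate, -0.5)
  expect_equal(one$std_err, 0.2)
  # equal weights: pooled SE shrinks by sqrt(2)
  two <- pool_fixed_iv(data.frame(estimate = c(0.3, 0.3), std_err = 0.2))
  expect_equal(two$estimate, 0.3)
  expect_equal(two$std_err, 0.2 / sqrt(2))
  expect_error(pool_fixed_iv(data.frame(treatment = c("B", "C"),
                                        reference = "A",
                                        estimate = 0, std_err = 1)),
               "mix comparisons")
})

test_that("Cochran's Q and I-squared match hand values", {
  q <- cochran_q(sor_pla())
  expect_equal(q$Q, 0.0055, tolerance = 1e-2)
  expect_equal(q$df, 1)
  expect_equal(q$I2, 0)
  # identical effects carry no heterogeneity
  q0 <- cochran_q(data.frame(estimate = rep(0.4, 4), std_err = 1))
  expect_equal(q0$Q, 0)
  expect_equal(q0$I2, 0)
  # two unit-weight effects 10 apart: Q = 25 + 25
  q2 <- cochran_q(data.frame(estimate = c(0, 10), std_err = 1))
  expect_equal(q2$Q, 50)
  expect_equal(q2$I2, 98)
  expect_error(cochran_q(data.frame(estimate = 1, std_err = 1)), "at least 2")
})

test_that("DerSimonian-Laird pooling truncates tau2 and re-weights", {
  # homogeneous pair: tau2 truncates to zero, result equals fixed effect
  dl <- pool_random_dl(sor_pla())
  fx <- pool_fixed_iv(sor_pla())
  expect_equal(dl$tau2, 0)
  expect_equal(dl$estimate, fx$estimate)
  expect_equal(dl$std_err, fx$std_err)
  # heterogeneous pair: tau2 = (50 - 1) / (2 - 2/2) = 49
  het <- pool_random_dl(data.frame(estimate = c(0, 10), std_err = 1))
  expect_equal(het$tau2, 49)
  expect_equal(het$estimate, 5)
  expect_equal(het$std_err, 5)
  # equal SEs with tau2 = 0 reduce to the arithmetic mean
  eq <- pool_random_dl(data.frame(estimate = c(0.1, 0.2, 0.3),
                                  std_err = 10))
  expect_equal(eq$estimate, 0.2)
})

test_that("random-effects SE never falls below the fixed-effect SE", {
  set.seed(31)
  for (i in 1:20) {
    k <- sample(2:8, 1)
    eff <- data.frame(estimate = rnorm(k, 0, 1),
                      std_err = runif(k, 0.05, 0.5))
    expect_gte(pool_random_dl(eff)$std_err, pool_fixed_iv(eff)$std_err)
    fx <- pool_fixed_iv(eff)
    expect_gte(fx$estimate, min(eff$estimate))
    expect_lte(fx$estimate, max(eff$estimate))
  }
})

test_that("Mantel-Haenszel pooling matches the crude 2x2 odds ratio", {
  arms <- data.frame(study = "s1", treatment = c("T", "C"),
                     events = c(10, 5), total = c(100, 100))
  res <- pool_mh_or(arms, treatment = "T", reference = "C")
  expect_equal(exp(res$estimate), (10 * 95) / (5 * 90))
  expect_equal(exp(res$estimate), 2.111, tolerance = 1e-3)
  # identical arms: OR exactly 1
  eq <- pool_mh_or(data.frame(study = "s1", treatment = c("T", "C"),
                              events = 8, total = 50),
                   treatment = "T", reference = "C")
  expect_equal(exp(eq$estimate), 1)
  # duplicating the table keeps the OR, tightens the SE
  two <- pool_mh_or(rbind(arms, within(arms, study <- "s2")),
                    treatment = "T", reference = "C")
  expect_equal(two$estimate, res$estimate)
  expect_lt(two$std_err, res$std_err)
  expect_error(pool_mh_or(data.frame(study = "s1", treatment = c("T", "C"),
                                     events = 0, total = 20)),
               "zero margin")
})

test_that("Mantel-Haenszel estimate and RBG variance agree with metafor", {
  skip_if_not_installed("metafor")
  set.seed(5)
  k <- 4
  arms <- do.call(rbind, lapply(seq_len(k), function(i) {
    n <- sample(50:200, 2)
    data.frame(study = paste0("s", i), treatment = c("T", "C"),
               events = rbinom(2, n, c(0.25, 0.15)), total = n)
  }))
  res <- pool_mh_or(arms, treatment = "T", reference = "C")
  tr <- arms[arms$treatment == "T", ]
  co <- arms[arms$treatment == "C", ]
  ref <- metafor::rma.mh(ai = tr$events, bi = tr$total - tr$events,
                         ci = co$events, di = co$total - co$events,
                         measure = "OR", add = 0, to = "none")
  expect_equal(res$estimate, as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(res$std_err, ref$se, tolerance = 1e-10)
})

test_that("DL and fixed-effect pooling agree with metafor", {
  skip_if_not_installed("metafor")
  eff <- sor_pla()
  dl <- metafor::rma(yi = eff$estimate, sei = eff$std_err, method = "DL")
  expect_equal(pool_random_dl(eff)$estimate, as.numeric(dl$beta),
               tolerance = 1e-10)
  fe <- metafor::rma(yi = eff$estimate, sei = eff$std_err, method = "FE")
  expect_equal(pool_fixed_iv(eff)$estimate, as.numeric(fe$beta),
               tolerance = 1e-10)
  het <- data.frame(estimate = c(-0.6, 0.1, 0.4, -0.2),
                    std_err = c(0.2, 0.3, 0.25, 0.15))
  dl2 <- metafor::rma(yi = het$estimate, sei = het$std_err, method = "DL")
  r2 <- pool_random_dl(het)
  expect_equal(r2$tau2, dl2$tau2, tolerance = 1e-10)
  expect_equal(r2$estimate, as.numeric(dl2$beta), tolerance = 1e-10)
})

test_that("the heterogeneity rule picks the model", {
  expect_equal(choose_model(0.60, 30), "fixed")
  expect_equal(choose_model(0.04, 50), "random")   # p branch alone
  expect_equal(choose_model(0.60, 51), "random")   # I2 branch alone
  expect_equal(choose_model(0.90, 0), "fixed")
})

test_that("pooling is order-invariant and ignores an uninformative study", {
  eff <- data.frame(estimate = c(-0.4, 0.1, 0.3), std_err = c(0.1, 0.2, 0.3))
  perm <- eff[c(3, 1, 2), ]
  expect_equal(cochran_q(eff)$Q, cochran_q(perm)$Q)
  expect_equal(pool_fixed_iv(eff)$estimate, pool_fixed_iv(perm)$estimate)
  # adding a study with essentially infinite SE leaves the fixed-effect
  # pool and Q unchanged (DL is excluded: its degrees of freedom count
  # studies, so tau2 legitimately moves)
  aug <- rbind(eff, data.frame(estimate = 5, std_err = 1e6))
  expect_lt(abs(pool_fixed_iv(aug)$estimate - pool_fixed_iv(eff)$estimate),
            1e-6)
  expect_lt(abs(cochran_q(aug)$Q - cochran_q(eff)$Q), 1e-6)
})

test_that("direct meta-analysis table covers every comparison with the rule applied", {
  sim <- simulate_contrast_network(sim_truth(seed = 3))
  dm <- direct_meta(sim$dataset)
  key <- unique(paste(sim$dataset$contrasts$treatment,
                      sim$dataset$contrasts$reference))
  expect_equal(nrow(dm), length(key))
  expect_true(all(dm$model %in% c("fixed", "random")))
  multi <- dm[dm$k_studies >= 2, ]
  expect_true(all(ifelse(multi$I2 > 50 | multi$p_Q < 0.05,
                         multi$model == "random", multi$model == "fixed")))
})
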