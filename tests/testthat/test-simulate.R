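test_that("generator matches its configured moments at large n", {
  cf <- sim_config(n_studies = 5000, effects_per_study = 2,
                   sigma2_ul = 0, sigma2_us = 0,
                   beta_l = c(intrcpt = 0.3),
                   beta_s = c(intrcpt = log(0.2)), seed = 61)
  sim <- simulate_meta(cf)
  y <- sim$table$yi
  n <- length(y)
  expect_equal(mean(y), 0.3, tolerance = 3 * sd(y) / sqrt(n))
  # total variance = residual (0.2^2) + average sampling variance
  target <- sqrt(0.04 + mean(sim$table$vi))
  expect_equal(sd(y), target, tolerance = 0.01)
})

test_that("study-mean variance reflects the between-study component", {
  cf <- sim_config(n_studies = 2000, effects_per_study = 4,
                   sigma2_ul = 0.25, sigma2_us = 0,
                   beta_s = c(intrcpt = log(0.2)), seed = 62)
  sim <- simulate_meta(cf)
  sm <- tapply(sim$table$yi, sim$table$study, mean)
  # var of study means = s2ul + (residual + mean v)/k
  expected <- 0.25 + (0.04 + mean(sim$table$vi)) / 4
  expect_lt(abs(var(as.numeric(sm)) - expected), 0.03)   # ~3 MC SEs
  # realized latent effects match their declared variance
  expect_lt(abs(var(sim$truth$u_l) - 0.25), 0.025)

})

test_that("degenerate correlation and determinism hold", {
  cf <- sim_config(n_studies = 400, effects_per_study = 2,
                   sigma2_ul = 0.3, sigma2_us = 0.3, rho_u = 1, seed = 63)
  sim <- simulate_meta(cf)
  expect_equal(cor(sim$truth$u_l, sim$truth$u_s), 1, tolerance = 1e-12)
  sim2 <- simulate_meta(cf)
  expect_identical(sim$table, sim2$table)
  expect_identical(sim$truth, sim2$truth)
  # the generator must not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(simulate_meta(cf)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(seed = 1, rho_u = 1.2), "rho_u")
  expect_error(sim_config(seed = 1, sigma2_ul = -1), "non-negative")
  expect_error(sim_config(), "seed")
})

test_that("fitting the generating model recovers parameters (large n)", {
  cf <- sim_config(n_studies = 800, effects_per_study = 3,
                   sigma2_ul = 0.25,
                   beta_l = c(intrcpt = 0.3, x = 0.2),
                   beta_s = c(intrcpt = log(0.3), x = 0.25),
                   moderators = list(x = list(type = "normal")), seed = 64)
  sim <- simulate_meta(cf)
  fit <- fit_reml_ml(sim$table, ~x, ~x, rho_m = 0)
  est <- coef(fit)
  # absolute bounds set at ~3 asymptotic SEs for this problem size
  expect_lt(abs(est[["location.intrcpt"]] - 0.3), 0.07)
  expect_lt(abs(est[["location.x"]] - 0.2), 0.06)
  expect_lt(abs(est[["scale.intrcpt"]] - log(0.3)), 0.12)
  expect_lt(abs(est[["scale.x"]] - 0.25), 0.12)
  expect_lt(abs(est[["sigma2_ul"]] - 0.25), 0.06)
})

test_that("recovery_study tabulates bias, RMSE and coverage", {
  cf <- sim_config(n_studies = 60, effects_per_study = 2, sigma2_ul = 0.2,
                   beta_s = c(intrcpt = log(0.3)), seed = 65)
  rs <- recovery_study(cf, n_reps = 8)
  expect_true(all(c("param", "truth", "bias", "rmse", "coverage") %in%
                    names(rs)))
  expect_true("scale.intrcpt" %in% rs$param)
  expect_equal(attr(rs, "failures"), 0L)
  expect_true(all(rs$rmse > 0))
})

test_that("operating_characteristics reports rejection rates with MC SEs", {
  null_cf <- sim_config(n_studies = 40, effects_per_study = 2,
                        sigma2_ul = 0.1,
                        beta_s = c(intrcpt = log(0.3)),
                        moderators = list(g = list(type = "categorical",
                                                   levels = c("a", "b"))),
                        seed = 66)
  alt_cf <- null_cf
  alt_cf$beta_s <- c(intrcpt = log(0.3), gb = log(3))
  oc <- operating_characteristics(null_cf, alt_cf, n_reps = 12,
                                  coefficient = "scale.gb")
  expect_equal(nrow(oc), 2L)
  expect_true(all(oc$rejection_rate >= 0 & oc$rejection_rate <= 1))
  # a 3-fold SD contrast should reject much more often than the null
  expect_gt(oc$rejection_rate[2], oc$rejection_rate[1])
  # degenerate alpha = 1 rejects everything
  oc1 <- operating_characteristics(null_cf, alt_cf, n_reps = 4,
                                   coefficient = "scale.gb", alpha = 1)
  expect_equal(oc1$rejection_rate, c(1, 1))
})
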