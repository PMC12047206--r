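# Module-level MCMC checks use short chains on small datasets; the full
# convergence-quality run lives in the acceptance suite.

test_that("posterior of sigma_us concentrates near zero when truth is zero", {
  # precisely estimated effects (small sampling variances) so the residual
  # scale, and hence the absence of scale heterogeneity, is well identified
  sim <- simulate_meta(sim_config(
    n_studies = 200, effects_per_study = 5, sigma2_ul = 0.25,
    sigma2_us = 0, rho_u = 0, beta_s = c(intrcpt = log(0.3)),
    v_dist = list(type = "uniform", min = 0.005, max = 0.05), seed = 5))
  fit <- fit_bayes(sim$table, ~1, ~1, rho_u = "zero",
                   mcmc = list(seed = 5, chains = 2, iter = 1500,
                               warmup = 800),
                   refit_on_nonconvergence = FALSE)
  row <- fit$par_table[fit$par_table$param == "sigma_us", ]
  expect_lt(row$ci.ub, 0.25)
})

test_that("with sigma_us fixed off, posterior means track REML estimates", {
  sim <- simulate_meta(sim_config(
    n_studies = 150, effects_per_study = 2, sigma2_ul = 0.2,
    sigma2_us = 0, beta_s = c(intrcpt = log(0.35)), seed = 9))
  reml <- fit_reml_ml(sim$table, ~1, ~1, rho_m = 0)
  bay <- fit_bayes(sim$table, ~1, ~1, scale_random_study = FALSE,
                   mcmc = list(seed = 9, chains = 2, iter = 800,
                               warmup = 500))
  expect_equal(unname(bay$beta_l["intrcpt"]), unname(reml$beta_l["intrcpt"]),
               tolerance = 0.05)
  expect_equal(unname(bay$beta_s["intrcpt"]), unname(reml$beta_s["intrcpt"]),
               tolerance = 0.15)
  expect_equal(bay$sigma2_ul, reml$sigma2_ul, tolerance = 0.3)
})

test_that("draws are reproducible from the seed and carry diagnostics", {
  sim <- simulate_meta(sim_config(n_studies = 40, effects_per_study = 2,
                                  sigma2_us = 0.2, seed = 3))
  m <- list(seed = 42, chains = 2, iter = 150, warmup = 150)
  f1 <- fit_bayes(sim$table, ~1, ~1, mcmc = m,
                  refit_on_nonconvergence = FALSE)
  f2 <- fit_bayes(sim$table, ~1, ~1, mcmc = m,
                  refit_on_nonconvergence = FALSE)
  expect_identical(f1$draws$draws, f2$draws$draws)
  expect_true(all(is.finite(f1$draws$rhat)))
  expect_equal(dim(f1$draws$draws), c(150L, 2L, 5L))
  # short chains like these must not be silently declared converged unless
  # the criteria genuinely hold
  expect_identical(f1$converged,
                   all(f1$draws$rhat < 1.01) && all(f1$draws$ess > 400))

  # heterogeneity and wald summaries propagate through posterior draws
  h <- heterogeneity(f1)
  expect_s3_class(h, "lsmeta_hetero_bayes")
  row <- h$summary[h$summary$stat == "i2_ls_between", ]
  expect_true(row$ci.lb <= row$mean && row$mean <= row$ci.ub)
  wt <- wald_test(f1, "scale.intrcpt")
  expect_true(wt$p_greater_than_null >= 0 && wt$p_greater_than_null <= 1)
})

test_that("single-effect-per-study data trigger the identifiability warning", {
  sim <- simulate_meta(sim_config(n_studies = 25, effects_per_study = 1,
                                  sigma2_us = 0.3, seed = 12))
  expect_warning(
    fit_bayes(sim$table, ~1, ~1,
              mcmc = list(seed = 2, chains = 2, iter = 100, warmup = 100),
              refit_on_nonconvergence = FALSE),
    "weakly identified")
})

test_that("missing seed is an error", {
  sim <- simulate_meta(sim_config(n_studies = 10, seed = 1))
  expect_error(fit_bayes(sim$table, mcmc = list(chains = 1)), "seed")
})
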