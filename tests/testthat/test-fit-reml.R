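test_that("intercept-only fit reproduces classical RE-REML exactly", {
  tab <- toy_table(J = 12, k = 1, seed = 21)
  fit <- suppressMessages(fit_reml_ml(tab))
  m <- metafor::rma(yi = tab$yi, vi = tab$vi, method = "REML")
  expect_lt(abs(exp(2 * unname(fit$beta_s["intrcpt"])) - m$tau2), 1e-6)
  expect_lt(abs(unname(fit$beta_l["intrcpt"]) - as.numeric(coef(m))), 1e-6)
  expect_lt(abs(fit$loglik - as.numeric(logLik(m))), 1e-5)
})

test_that("multilevel fit agrees with an independent multilevel REML", {
  sim <- simulate_meta(sim_config(n_studies = 40, effects_per_study = 3,
                                  sigma2_ul = 0.2,
                                  beta_s = c(intrcpt = log(0.3)),
                                  seed = 31))
  tab <- sim$table
  fit <- fit_reml_ml(tab, ~1, ~1, rho_m = 0)
  m <- metafor::rma.mv(yi, vi, random = ~ 1 | study / effect_id,
                       data = as.data.frame(tab), method = "REML")
  expect_equal(fit$sigma2_ul, m$sigma2[1], tolerance = 1e-4)
  expect_equal(exp(2 * unname(fit$beta_s["intrcpt"])), m$sigma2[2],
               tolerance = 1e-4)
  expect_equal(unname(fit$beta_l["intrcpt"]), as.numeric(coef(m)),
               tolerance = 1e-6)
})

test_that("meta-regression with a shared-subject V matches metafor", {
  sim <- simulate_meta(sim_config(
    n_studies = 30, effects_per_study = 2, sigma2_ul = 0.15,
    beta_l = c(intrcpt = 0.2, x = 0.3), beta_s = c(intrcpt = log(0.25)),
    moderators = list(x = list(type = "normal")),
    rho_m = 0.5, subject_groups = TRUE, seed = 77))
  tab <- sim$table
  V <- build_sampling_vcov(tab, rho_m = 0.5)
  fit <- fit_reml_ml(tab, ~x, ~1, V = V)
  Vm <- metafor::vcalc(vi, cluster = study, obs = effect_id, rho = 0.5,
                       data = as.data.frame(tab))
  m <- metafor::rma.mv(yi, V = Vm, mods = ~x,
                       random = ~ 1 | study / effect_id,
                       data = as.data.frame(tab), method = "REML")
  expect_equal(unname(fit$beta_l), unname(coef(m)), tolerance = 1e-4)
  expect_equal(fit$sigma2_ul, m$sigma2[1], tolerance = 1e-3)
})

test_that("null between-study variance is recovered at the boundary", {
  set.seed(55)
  n <- 200
  v <- runif(n, 0.02, 0.1)
  y <- 0.1 + rnorm(n, 0, 0.15) + rnorm(n, 0, sqrt(v))
  tab <- effect_table(data.frame(yi = y, vi = v,
                                 study = rep(paste0("s", 1:50), each = 4)))
  fit <- fit_reml_ml(tab, ~1, ~1)
  # data have no true study-level variance: estimate at/near zero boundary
  expect_lt(fit$sigma2_ul, 0.01)
})

test_that("a true scale slope is recovered within its own interval", {
  sim <- simulate_meta(sim_config(
    n_studies = 167, effects_per_study = 3, sigma2_ul = 0.25,
    beta_l = c(intrcpt = 0.3), beta_s = c(intrcpt = log(0.3), x = 0.3),
    moderators = list(x = list(type = "normal")), seed = 1))
  fit <- fit_reml_ml(sim$table, ~x, ~x)
  row <- fit$par_table[fit$par_table$param == "scale.x", ]
  expect_gt(0.3, row$ci.lb)
  expect_lt(0.3, row$ci.ub)
})

test_that("location shift moves only the location intercept", {
  sim <- simulate_meta(sim_config(n_studies = 40, effects_per_study = 3,
                                  sigma2_ul = 0.2,
                                  beta_s = c(intrcpt = log(0.3)),
                                  seed = 13))
  tab <- sim$table
  f1 <- fit_reml_ml(tab, ~1, ~1, rho_m = 0)
  df <- as.data.frame(tab); df$yi <- df$yi + 2.5
  f2 <- fit_reml_ml(effect_table(df[, setdiff(names(df), "effect_id")]),
                    ~1, ~1, rho_m = 0)
  expect_equal(unname(f2$beta_l["intrcpt"] - f1$beta_l["intrcpt"]), 2.5,
               tolerance = 1e-6)
  expect_equal(f2$beta_s, f1$beta_s, tolerance = 1e-5)
  expect_equal(f2$sigma2_ul, f1$sigma2_ul, tolerance = 1e-5)
})

test_that("ML dominates any restricted parameterization it nests", {
  tab <- toy_table(J = 10, k = 2, seed = 17)
  full <- fit_reml_ml(tab, ~1, ~1, method = "ml")
  # restricted: no study random effect
  restr <- fit_reml_ml(tab, ~1, ~1, method = "ml", random_study = FALSE)
  expect_gte(full$loglik, restr$loglik - 1e-6)
  # and the maximized ML is at least the likelihood at arbitrary points
  for (b0s in c(-2, -1, 0)) {
    expect_gte(full$loglik,
               marginal_loglik(tab, ~1, ~1, beta_s = b0s, sigma2_ul = 0.05,
                               method = "ml"))
  }
})

test_that("cluster-robust SEs behave as theory predicts", {
  # correctly specified model: robust and model SEs agree at large K
  sim <- simulate_meta(sim_config(n_studies = 500, effects_per_study = 1,
                                  sigma2_ul = 0, sigma2_us = 0,
                                  beta_s = c(intrcpt = log(0.3)), seed = 2))
  fit <- suppressMessages(fit_reml_ml(sim$table, ~1, ~1))
  Vr <- cluster_robust_vcov(fit)
  ratio <- attr(Vr, "se")[1] / sqrt(fit$vcov_l[1, 1])
  expect_gt(ratio, 0.8); expect_lt(ratio, 1.2)

  # ignored within-study dependence: robust SEs exceed model SEs
  set.seed(8)
  J <- 80
  u <- rnorm(J, 0, 0.5)
  y <- 0.2 + rep(u, each = 4) + rnorm(4 * J, 0, 0.1)
  tab <- effect_table(data.frame(yi = y, vi = rep(0.04, 4 * J),
                                 study = rep(paste0("s", 1:J), each = 4)))
  bad <- fit_reml_ml(tab, ~1, ~1, random_study = FALSE)  # dependence ignored
  Vr2 <- cluster_robust_vcov(bad)
  expect_gt(attr(Vr2, "se")[1], sqrt(bad$vcov_l[1, 1]))

  # fewer clusters than coefficients: warning path
  small <- effect_table(data.frame(yi = rnorm(6), vi = rep(0.1, 6),
                                   study = rep(c("a", "b"), each = 3),
                                   x = rnorm(6), z = rnorm(6)))
  fs <- fit_reml_ml(small, ~ x + z, ~1)
  expect_warning(cluster_robust_vcov(fs), "unreliable")
})

test_that("wald_test reports sensible z-tests and errors", {
  tab <- toy_table(J = 10, k = 2, seed = 19)
  fit <- fit_reml_ml(tab, ~1, ~1)
  wt <- wald_test(fit, "location.intrcpt",
                  null = unname(fit$beta_l["intrcpt"]))
  expect_equal(wt$pval, 1, tolerance = 1e-10)
  expect_error(wald_test(fit, "scale.bogus"), "unknown coefficient")
})
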