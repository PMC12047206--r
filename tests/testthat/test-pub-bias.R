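test_that("bias moderators are constructed as declared", {
  tab <- effect_table(data.frame(yi = c(0.1, 0.2, 0.3),
                                 vi = c(0.04, 0.09, 0.16),
                                 study = c("a", "b", "c"),
                                 year = c(2000, 2010, 2020)),
                      year = "year")
  out <- build_bias_moderators(tab, "se")
  expect_equal(out$se, c(0.2, 0.3, 0.4))
  expect_equal(out$cyear, c(-10, 0, 10))
  expect_equal(attr(out, "year_center"), 2010)

  es <- effective_sample_size("SMD", c(20, 40, 10), c(20, 40, 10))
  out2 <- build_bias_moderators(tab, "inv_sqrt_n", n_eff = es$n_eff)
  expect_equal(out2$inv_sqrt_n[1], 1 / sqrt(10))

  out3 <- build_bias_moderators(tab, "se", year_center = 2005)
  expect_equal(out3$cyear, c(-5, 5, 15))

  tab_ny <- effect_table(data.frame(yi = 0.1, vi = 0.01, study = "a"))
  expect_error(build_bias_moderators(tab_ny), "year")
})

test_that("four-way test reports all four coefficients with verdicts", {
  sim <- simulate_meta(sim_config(
    n_studies = 80, effects_per_study = 2, sigma2_ul = 0.1,
    beta_l = c(intrcpt = 0.3),
    beta_s = c(intrcpt = log(0.25)),
    moderators = list(yr = list(type = "year", from = 2000, to = 2020)),
    seed = 71))
  bt <- four_way_bias_test(sim$table, rho_m = 0)
  expect_s3_class(bt, "lsmeta_bias")
  expect_equal(bt$report$test,
               c("small-study effect", "decline effect",
                 "small-study divergence", "Proteus effect"))
  expect_equal(bt$report$part, c("location", "location", "scale", "scale"))
  expect_true(all(is.finite(bt$report$estimate)))
  expect_type(bt$report$detected, "logical")
})

test_that("an injected Proteus effect is detected on the scale part", {
  # variance increasing with publication year, no location trend
  sim <- simulate_meta(sim_config(
    n_studies = 150, effects_per_study = 2, sigma2_ul = 0.1,
    beta_l = c(intrcpt = 0.3),
    beta_s = c(intrcpt = log(0.3), yr = 0.08),
    moderators = list(yr = list(type = "year", from = 2000, to = 2020)),
    seed = 72))
  bt <- four_way_bias_test(sim$table, rho_m = 0)
  rep <- bt$report
  expect_true(rep$detected[rep$test == "Proteus effect"])
  expect_gt(rep$estimate[rep$test == "Proteus effect"], 0)
})

test_that("degenerate inputs are refused with clear messages", {
  sim <- simulate_meta(sim_config(
    n_studies = 60, effects_per_study = 1,
    v_dist = list(type = "fixed", values = 0.04),
    moderators = list(yr = list(type = "year", from = 2000, to = 2020)),
    seed = 73))
  # constant sampling variance makes the se axis constant
  expect_error(suppressWarnings(four_way_bias_test(sim$table, rho_m = 0)),
               "constant")
  # constant effective sample size likewise
  expect_error(
    suppressWarnings(four_way_bias_test(sim$table, choice = "inv_sqrt_n",
                                        n_eff = rep(25, 60), rho_m = 0)),
    "constant")

  sim2 <- simulate_meta(sim_config(n_studies = 5, effects_per_study = 1,
                                   moderators = list(
                                     yr = list(type = "year")), seed = 74))
  expect_error(four_way_bias_test(sim2$table), "at least 10")

  sim3 <- simulate_meta(sim_config(n_studies = 20, effects_per_study = 1,
                                   moderators = list(
                                     yr = list(type = "year")), seed = 75))
  expect_warning(four_way_bias_test(sim3$table, rho_m = 0), "unstable")
})

test_that("scale-part bias slopes ignore location shifts", {
  sim <- simulate_meta(sim_config(
    n_studies = 80, effects_per_study = 2, sigma2_ul = 0.1,
    moderators = list(yr = list(type = "year", from = 2000, to = 2020)),
    seed = 76))
  b1 <- four_way_bias_test(sim$table, rho_m = 0)
  df <- as.data.frame(sim$table); df$yi <- df$yi + 3
  tab2 <- effect_table(df[, setdiff(names(df), "effect_id")], year = "year")
  b2 <- four_way_bias_test(tab2, rho_m = 0)
  sc1 <- b1$report[b1$report$part == "scale", "estimate"]
  sc2 <- b2$report[b2$report$part == "scale", "estimate"]
  expect_equal(sc1, sc2, tolerance = 1e-3)
})
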