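test_that("two-level I2 follows its defining ratio", {
  expect_equal(i2_two_level(3, 1), 0.75)
  expect_equal(i2_two_level(0, 1), 0)
  expect_equal(i2_two_level(0.37, 0.37), 0.5)
  expect_error(i2_two_level(0, 0), "undefined")
})

test_that("multilevel I2 partitions and is additive", {
  out <- i2_multilevel(2, 1, 1)
  expect_equal(unname(out), c(0.5, 0.25, 0.75))
  expect_equal(unname(i2_multilevel(0, 0, 1)), c(0, 0, 0))
  set.seed(2)
  for (i in 1:200) {
    x <- runif(3, 0, 5)
    out <- i2_multilevel(x[1], x[2], x[3])
    expect_equal(out[["i2_between"]] + out[["i2_within"]],
                 out[["i2_total"]])
    expect_true(all(out >= 0 & out <= 1))
  }
})

test_that("log-normal typical residual variance is exp(2b0s + 2s2us)", {
  expect_equal(sigma2_e_bar_ls(0, 0), 1)
  expect_equal(sigma2_e_bar_ls(0, 0.5), exp(1))
  expect_equal(sigma2_e_bar_ls(log(2), 0), 4)
})

test_that("location-scale between-study I2 behaves and reduces correctly", {
  # beta0_s = 0, s2us = 0 gives sigma2_e_bar = 1
  expect_equal(i2_ls_between(1, 0, 0, 1), 1 / 3)
  expect_equal(i2_ls_between(0, 0.3, 0.1, 1), 0)
  # monotone decreasing in the scale-effect variance
  vals <- sapply(c(0, 0.2, 0.5, 1), function(s)
    i2_ls_between(1, 0, s, 1))
  expect_true(all(diff(vals) < 0))
  # with s2us = 0 it equals the multilevel between-study I2 exactly
  set.seed(4)
  for (i in 1:100) {
    s2u <- runif(1, 0, 3); se <- runif(1, 0.1, 2); vb <- runif(1, 0.01, 1)
    expect_equal(i2_ls_between(s2u, log(se), 0, vb),
                 i2_multilevel(s2u, se^2, vb)[["i2_between"]])
  }
})

test_that("CVH family satisfies the Pythagorean identity", {
  expect_equal(cvh_family(1, 0, 2)[["cvh_between"]], 0.5)
  expect_equal(unname(cvh_family(0, 0, 1)), c(0, 0, 0))
  out <- cvh_family(3, 4, 1)
  expect_equal(out[["cvh_total"]], 5)
  set.seed(6)
  for (i in 1:200) {
    su <- runif(1, 0, 3); se <- runif(1, 0, 3); b0 <- runif(1, 0.1, 2)
    out <- cvh_family(su, se, b0)
    expect_equal(out[["cvh_between"]]^2 + out[["cvh_within"]]^2,
                 out[["cvh_total"]]^2)
  }
  expect_warning(res <- cvh_family(1, 1, 0), "undefined")
  expect_true(all(is.na(res)))
})

test_that("location/scale CVs follow the log-normal CV formula", {
  expect_equal(cvh_location_scale(1, 2, 0)[["cvh_scale"]], 0)
  expect_equal(cvh_location_scale(1, 2, log(2))[["cvh_scale"]], 1)
  expect_equal(cvh_location_scale(1, 2, 1)[["cvh_scale"]], sqrt(exp(1) - 1))
  # variance-scale variant inflates the argument fourfold
  expect_equal(cvh_location_scale(1, 2, 0.3, variance_scale = TRUE)[["cvh_scale"]],
               sqrt(exp(1.2) - 1))
})

test_that("phylogenetic heritability is the phylogenetic variance share", {
  expect_equal(phylo_heritability(0.3, 0.3), 0.5)
  expect_equal(phylo_heritability(0.3, 0), 1)
  expect_equal(phylo_heritability(0.4, 0.1), 0.8)
  expect_error(phylo_heritability(0, 0), "undefined")
})

test_that("heterogeneity() summarizes a fitted model coherently", {
  sim <- simulate_meta(sim_config(n_studies = 60, effects_per_study = 3,
                                  sigma2_ul = 0.3,
                                  beta_s = c(intrcpt = log(0.3)), seed = 14))
  fit <- fit_reml_ml(sim$table, ~1, ~1, rho_m = 0)
  h <- heterogeneity(fit)
  expect_equal(h$i2_between + h$i2_within, h$i2_total)
  expect_equal(h$v_bar, typical_sampling_variance(sim$table$vi))
  expect_true(h$i2_total >= 0 && h$i2_total <= 1)
  # i2 from the fit should reflect substantial simulated heterogeneity
  expect_gt(h$i2_total, 0.5)
})
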