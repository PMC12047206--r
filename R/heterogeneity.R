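# Relative heterogeneity statistics: the classical two-level I2, its
# multilevel partition, the location-scale extension whose typical
# residual variance is a log-normal mean, and the mean-standardized
# (coefficient-of-variation) CVH family.

#' Two-level I-squared
#'
#' \eqn{I^2 = \sigma^2_e / (\sigma^2_e + \bar\sigma^2_m)}: the share of
#' total variance due to between-study heterogeneity, relative to the
#' typical sampling variance \code{v_bar}
#' (\code{\link{typical_sampling_variance}}).
#'
#' @param sigma2_e between-study (heterogeneity) variance.
#' @param v_bar typical sampling variance.
#' @return I-squared in [0, 1].
#' @export
i2_two_level <- function(sigma2_e, v_bar) {
  if (sigma2_e < 0 || v_bar < 0) .stopf("variances must be non-negative")
  if (sigma2_e + v_bar == 0) .stopf("both variances are zero; I2 undefined")
  sigma2_e / (sigma2_e + v_bar)
}

#' Multilevel I-squared partition
#'
#' With effect sizes nested in studies, heterogeneity splits into a
#' between-study component \code{sigma2_u} and a within-study component
#' \code{sigma2_e}; all three ratios share the denominator
#' \eqn{\sigma^2_u + \sigma^2_e + \bar\sigma^2_m}, so the between and
#' within I-squared add up exactly to the total.
#'
#' @param sigma2_u between-study variance.
#' @param sigma2_e within-study (effect-level) variance.
#' @param v_bar typical sampling variance.
#' @return named vector \code{c(i2_between, i2_within, i2_total)}.
#' @export
i2_multilevel <- function(sigma2_u, sigma2_e, v_bar) {
  if (any(c(sigma2_u, sigma2_e, v_bar) < 0))
    .stopf("variances must be non-negative")
  den <- sigma2_u + sigma2_e + v_bar
  if (den == 0) .stopf("zero denominator; I2 undefined")
  ib <- sigma2_u / den
  iw <- sigma2_e / den
  # the total is defined as the sum, keeping the partition exact
  c(i2_between = ib, i2_within = iw, i2_total = ib + iw)
}

#' Typical residual variance of a location-scale model
#'
#' With the residual log-SD modelled as \code{beta0_s + u_s},
#' \code{u_s ~ N(0, sigma2_us)}, the residual variance is log-normal and
#' its mean is \eqn{\bar\sigma^2_e = \exp(2\beta_{0s} + 2\sigma^2_{us})}.
#'
#' @param beta0_s scale-part intercept (log residual SD).
#' @param sigma2_us between-study variance in the scale part.
#' @return the typical residual variance.
#' @export
sigma2_e_bar_ls <- function(beta0_s, sigma2_us = 0) {
  if (any(sigma2_us < 0)) .stopf("sigma2_us must be non-negative")
  exp(2 * beta0_s + 2 * sigma2_us)  # vectorized over posterior draws
}

#' Between-study I-squared for a location-scale model
#'
#' \eqn{I^2_B = \sigma^2_{ul} / (\sigma^2_{ul} + \bar\sigma^2_e +
#' \bar\sigma^2_m)} with \eqn{\bar\sigma^2_e} from
#' \code{\link{sigma2_e_bar_ls}}. With \code{sigma2_us = 0} and
#' \code{beta0_s = log(sigma_e)} this reduces exactly to the multilevel
#' between-study I-squared.
#'
#' @param sigma2_ul between-study location variance.
#' @param beta0_s scale intercept.
#' @param sigma2_us between-study scale variance.
#' @param v_bar typical sampling variance.
#' @return I-squared (between-study) in [0, 1].
#' @export
i2_ls_between <- function(sigma2_ul, beta0_s, sigma2_us, v_bar) {
  if (sigma2_ul < 0 || sigma2_us < 0 || v_bar < 0)
    .stopf("variances must be non-negative")
  den <- sigma2_ul + sigma2_e_bar_ls(beta0_s, sigma2_us) + v_bar
  if (den == 0) .stopf("zero denominator; I2 undefined")
  sigma2_ul / den
}

#' Mean-standardized heterogeneity (CVH family)
#'
#' Heterogeneity standard deviations divided by the absolute mean effect:
#' \code{CVHB = sigma_u/|beta0|}, \code{CVHW = sigma_e/|beta0|},
#' \code{CVHT = sqrt(sigma_u^2 + sigma_e^2)/|beta0|}, so
#' \code{CVHB^2 + CVHW^2 = CVHT^2}. Undefined (reported as \code{NA}
#' with a warning) when \code{|beta0|} is numerically zero, since these
#' ratios presume ratio-scale-like behaviour of the mean.
#'
#' @param sigma_u between-study SD.
#' @param sigma_e within-study SD.
#' @param beta0_abs absolute overall mean |beta0|.
#' @return named vector \code{c(cvh_between, cvh_within, cvh_total)}.
#' @export
cvh_family <- function(sigma_u, sigma_e, beta0_abs) {
  if (sigma_u < 0 || sigma_e < 0) .stopf("SDs must be non-negative")
  if (beta0_abs < 1e-8) {
    .warnf("|beta0| is numerically zero; CVH is undefined")
    return(c(cvh_between = NA_real_, cvh_within = NA_real_,
             cvh_total = NA_real_))
  }
  cb <- sigma_u / beta0_abs
  cw <- sigma_e / beta0_abs
  c(cvh_between = cb, cvh_within = cw,
    cvh_total = sqrt(cb^2 + cw^2))
}

#' Location- and scale-part CVH for double-hierarchical models
#'
#' For the model with study effects in both parts, the location-part
#' between-study CV is \code{sigma_ul/|beta0|}, and the scale-part CV is
#' the coefficient of variation of the log-normal residual SD,
#' \eqn{\sqrt{\exp(\sigma^2_{us}) - 1}}. Because the scale part models
#' the log SD, the variance-scale variant uses \eqn{4\sigma^2_{us}}.
#'
#' @param sigma_ul between-study location SD.
#' @param beta0_abs absolute overall mean.
#' @param sigma2_us between-study scale variance.
#' @param variance_scale if \code{TRUE}, return the CV of the residual
#'   variance (uses \code{4 * sigma2_us}) instead of the SD.
#' @return named vector \code{c(cvh_location, cvh_scale)};
#'   \code{cvh_location} is \code{NA} (with a warning) when
#'   \code{|beta0|} is numerically zero.
#' @export
cvh_location_scale <- function(sigma_ul, beta0_abs, sigma2_us,
                               variance_scale = FALSE) {
  if (sigma_ul < 0 || sigma2_us < 0)
    .stopf("variance components must be non-negative")
  loc <- if (beta0_abs < 1e-8) {
    .warnf("|beta0| is numerically zero; location CVH is undefined")
    NA_real_
  } else sigma_ul / beta0_abs
  s2 <- if (variance_scale) 4 * sigma2_us else sigma2_us
  c(cvh_location = loc, cvh_scale = sqrt(exp(s2) - 1))
}

#' Phylogenetic heritability (lambda / H-squared)
#'
#' The share of species-level variance attributable to phylogeny:
#' \eqn{\lambda = H^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_s)}.
#'
#' @param sigma2_a phylogenetic variance.
#' @param sigma2_s non-phylogenetic species variance.
#' @return lambda in [0, 1].
#' @export
phylo_heritability <- function(sigma2_a, sigma2_s) {
  if (sigma2_a < 0 || sigma2_s < 0) .stopf("variances must be non-negative")
  if (sigma2_a + sigma2_s == 0)
    .stopf("both species-level variances are zero; lambda undefined")
  sigma2_a / (sigma2_a + sigma2_s)
}

#' Heterogeneity report for a fitted model
#'
#' Computes all applicable relative-heterogeneity statistics from a
#' fitted location-scale model: the multilevel I-squared partition (using
#' \code{exp(2 beta0_s)} as the residual variance at the scale-part
#' reference level), the location-scale between-study I-squared, the CVH
#' family, location/scale CVHs when a scale random effect was modelled,
#' and the phylogenetic heritability for phylogenetic fits. For Bayesian
#' fits every statistic is computed per posterior draw and summarized by
#' its posterior mean and central 95\% interval.
#'
#' @param fit an \code{"lsmeta_fit"} or \code{"lsmeta_bayes"} object.
#' @param v_bar typical sampling variance; default computed from the
#'   fitted data.
#' @return an object of class \code{"lsmeta_hetero"} (a named list of
#'   statistics, or a summary data.frame for Bayesian fits).
#' @export
heterogeneity <- function(fit, v_bar = NULL) {
  v_bar <- v_bar %||% typical_sampling_variance(fit$ctx$v %||% fit$data$vi)
  if (inherits(fit, "lsmeta_bayes")) return(.hetero_bayes(fit, v_bar))

  b0s <- unname(fit$beta_s["intrcpt"])
  b0l <- unname(fit$beta_l["intrcpt"])
  s2e <- exp(2 * b0s)
  s2u <- if (is.na(fit$sigma2_ul)) 0 else fit$sigma2_ul
  out <- list(v_bar = v_bar, sigma2_e = s2e, sigma2_ul = s2u)
  out$i2 <- i2_two_level(s2u + s2e, v_bar)
  out <- c(out, as.list(i2_multilevel(s2u, s2e, v_bar)))
  out$i2_ls_between <- i2_ls_between(s2u, b0s, 0, v_bar)
  out <- c(out, as.list(cvh_family(sqrt(s2u), sqrt(s2e), abs(b0l))))
  if (!is.na(fit$sigma2_a) && !is.na(fit$sigma2_s) &&
      fit$sigma2_a + fit$sigma2_s > 0)
    out$lambda_h2 <- phylo_heritability(fit$sigma2_a, fit$sigma2_s)
  structure(out, class = "lsmeta_hetero")
}

.hetero_bayes <- function(fit, v_bar) {
  dr <- .draws_matrix(fit$draws)
  b0l <- dr[, "location.intrcpt"]
  b0s <- dr[, "scale.intrcpt"]
  s2u <- dr[, "sigma_ul"]^2
  s2us <- dr[, "sigma_us"]^2
  s2e_bar <- sigma2_e_bar_ls(b0s, s2us)
  stats <- cbind(
    i2_ls_between = s2u / (s2u + s2e_bar + v_bar),
    sigma2_e_bar = s2e_bar,
    cvh_location = ifelse(abs(b0l) < 1e-8, NA_real_, sqrt(s2u) / abs(b0l)),
    cvh_scale = sqrt(exp(s2us) - 1))
  sm <- data.frame(
    stat = colnames(stats),
    mean = colMeans(stats, na.rm = TRUE),
    ci.lb = apply(stats, 2, stats::quantile, 0.025, na.rm = TRUE),
    ci.ub = apply(stats, 2, stats::quantile, 0.975, na.rm = TRUE),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(summary = sm, v_bar = v_bar, draws = stats),
            class = c("lsmeta_hetero_bayes", "lsmeta_hetero"))
}

#' @export
print.lsmeta_hetero <- function(x, ...) {
  if (inherits(x, "lsmeta_hetero_bayes")) {
    cat("Heterogeneity statistics (posterior summaries):\n")
    print(x$summary, digits = 4)
    return(invisible(x))
  }
  cat("Heterogeneity statistics:\n")
  num <- x[vapply(x, is.numeric, TRUE)]
  print(unlist(num), digits = 4)
  invisible(x)
}
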