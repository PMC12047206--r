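#' Construct publication-bias moderators
#'
#' Adds to the table the two regressors used by funnel-asymmetry and
#' time-trend bias tests: a small-study axis (either the standard error
#' \code{se = sqrt(v)}, or \code{1/sqrt(n_eff)} from effective sample
#' sizes, which avoids the intrinsic estimate/SE correlation of SMD-type
#' effect sizes) and the mean-centered publication year \code{cyear}.
#'
#' @param table an \code{\link{effect_table}} with a \code{year} column
#'   (needed for \code{cyear}).
#' @param choice \code{"se"} (default) or \code{"inv_sqrt_n"}.
#' @param n_eff effective sample sizes (vector aligned to rows), required
#'   for \code{choice = "inv_sqrt_n"}; see
#'   \code{\link{effective_sample_size}}.
#' @param year_center \code{"mean"} or a numeric year.
#' @return the table with added columns \code{se} or \code{inv_sqrt_n},
#'   and \code{cyear}; attribute \code{"year_center"} records the center.
#' @export
build_bias_moderators <- function(table, choice = c("se", "inv_sqrt_n"),
                                  n_eff = NULL, year_center = "mean") {
  stopifnot(inherits(table, "effect_table"))
  choice <- match.arg(choice)
  if (is.null(table$year)) .stopf("a 'year' column is required for cyear")
  at <- attributes(table)
  if (choice == "se") {
    table$se <- sqrt(table$vi)
  } else {
    if (is.null(n_eff)) .stopf("choice = 'inv_sqrt_n' needs n_eff")
    if (length(n_eff) != nrow(table))
      .stopf("n_eff must have one value per effect size")
    table$inv_sqrt_n <- 1 / sqrt(n_eff)
  }
  cy <- if (identical(year_center, "mean"))
    center_covariate(table$year, "mean")
  else center_covariate(table$year, "value", center = year_center)
  table$cyear <- as.numeric(cy)
  out <- structure(as.data.frame(table),
                   n_effects = at$n_effects, n_studies = at$n_studies,
                   moderators = union(at$moderators,
                                      c(if (choice == "se") "se"
                                        else "inv_sqrt_n", "cyear")),
                   year_center = attr(cy, "center"),
                   class = c("effect_table", "data.frame"))
  out
}

#' Four-way location-scale publication-bias test
#'
#' Fits the multilevel location-scale meta-regression with the
#' small-study axis and centered publication year in \emph{both} model
#' parts (plus any user moderators), and reports the four bias
#' coefficients: (a) small-study effect (location on the axis), (b)
#' decline effect (location on year), (c) small-study divergence (scale
#' on the axis), (d) Proteus effect (scale on year). Verdicts are based
#' on the 95\% interval excluding zero; the four hypotheses are distinct
#' a-priori tests, so no multiplicity correction is applied.
#'
#' Testing bias in the scale part matters in its own right: a pure
#' small-study divergence (heteroscedasticity increasing with SE) can
#' masquerade as funnel asymmetry in a standard meta-regression that
#' ignores it.
#'
#' @param table an \code{\link{effect_table}} with \code{year}.
#' @param extra_moderators character vector of additional moderator names
#'   to adjust for (entered in both parts).
#' @param choice small-study axis, \code{"se"} or \code{"inv_sqrt_n"}.
#' @param n_eff effective sample sizes for \code{"inv_sqrt_n"}.
#' @param year_center \code{"mean"} or a numeric year.
#' @param method \code{"reml"} (default), \code{"ml"} or \code{"bayes"}.
#' @param rho_m assumed sampling correlation (REML/ML path).
#' @param mcmc MCMC settings when \code{method = "bayes"}.
#' @param min_effects warn below this many effect sizes (default 40, a
#'   commonly cited minimum for stable location-scale fits); error below
#'   10.
#' @return an object of class \code{"lsmeta_bias"}: the four-row report
#'   plus the underlying fit.
#' @export
four_way_bias_test <- function(table, extra_moderators = character(),
                               choice = c("se", "inv_sqrt_n"), n_eff = NULL,
                               year_center = "mean", method = "reml",
                               rho_m = 0.5, mcmc = list(),
                               min_effects = 40L) {
  choice <- match.arg(choice)
  K <- nrow(table)
  if (K < 10L) .stopf("need at least 10 effect sizes for the bias test")
  if (K < min_effects)
    .warnf("only %d effect sizes; location-scale bias tests are unstable below ~%d",
           K, min_effects)
  tab <- build_bias_moderators(table, choice, n_eff = n_eff,
                               year_center = year_center)
  axis <- if (choice == "se") "se" else "inv_sqrt_n"

  ax <- tab[[axis]]
  if (stats::sd(ax) < 1e-12)
    .stopf("the small-study axis '%s' is constant; its slope is not identifiable",
           axis)
  ctr <- abs(stats::cor(ax, tab$cyear))
  if (is.na(ctr) || ctr > 0.95)
    .stopf("small-study axis and publication year are collinear (|r| = %.2f); the four tests cannot be separated", ctr)

  terms <- c(axis, "cyear", extra_moderators)
  form <- stats::as.formula(paste("~", paste(terms, collapse = "+")))
  fit <- if (identical(method, "bayes"))
    fit_bayes(tab, form, form, mcmc = mcmc)
  else
    suppressMessages(fit_reml_ml(tab, form, form, method = method,
                                 rho_m = rho_m))

  grab <- function(part, nm, label) {
    w <- wald_test(fit, paste0(part, ".", nm))
    data.frame(test = label, part = part, moderator = nm,
               estimate = w$estimate, ci.lb = w$ci.lb, ci.ub = w$ci.ub,
               detected = (w$ci.lb > 0 | w$ci.ub < 0),
               stringsAsFactors = FALSE)
  }
  report <- rbind(
    grab("location", axis, "small-study effect"),
    grab("location", "cyear", "decline effect"),
    grab("scale", axis, "small-study divergence"),
    grab("scale", "cyear", "Proteus effect"))

  structure(list(report = report, fit = fit, axis = axis,
                 year_center = attr(tab, "year_center")),
            class = "lsmeta_bias")
}

#' @export
print.lsmeta_bias <- function(x, ...) {
  cat("Four-way location-scale publication-bias test\n")
  cat(sprintf("small-study axis: %s; year centered at %.1f\n",
              x$axis, x$year_center))
  print(x$report, digits = 3)
  invisible(x)
}
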