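#' Fit a location-scale meta-regression by REML or ML
#'
#' Maximizes the marginal (restricted) likelihood over the scale
#' coefficients and the log variance components, with the location
#' coefficients profiled out by generalized least squares at each step.
#' The scale part models the log residual standard deviation as a linear
#' function of moderators; the location part models the mean. Random
#' effects in the scale part require the Bayesian path
#' (\code{\link{fit_bayes}}); here the scale part is fixed-effects only.
#'
#' With one effect size per study and an intercept-only scale part, the
#' between-study variance and \code{exp(2 beta0_s)} are not separately
#' identifiable (the classical random-effects model has a single
#' heterogeneity variance). In that case the study random effect is
#' dropped with a message and the scale intercept absorbs the whole
#' heterogeneity, so \code{exp(2 beta0_s)} estimates the classical tau^2.
#'
#' @param data an \code{\link{effect_table}}.
#' @param location,scale one-sided model formulas.
#' @param method \code{"reml"} (default) or \code{"ml"}.
#' @param random_study include a between-study random intercept in the
#'   location part.
#' @param rho_m assumed sampling correlation for the internally built
#'   \code{V}; ignored when \code{V} is supplied.
#' @param V optional sampling covariance from
#'   \code{\link{build_sampling_vcov}}.
#' @param phylo optional \code{\link{newick_to_phylo_corr}} object; adds a
#'   phylogenetic species effect (and a non-phylogenetic species effect)
#'   to the location part.
#' @param species_effect add a non-phylogenetic species random effect
#'   (implied by \code{phylo}).
#' @param control list: \code{n_starts} (default 5 deterministic
#'   multi-starts), \code{rel_tol} (objective tolerance, default 1e-8).
#' @return an object of class \code{"lsmeta_fit"}; see
#'   \code{\link{summary.lsmeta_fit}}. Key components: \code{beta_l},
#'   \code{beta_s} with covariances, \code{sigma2_ul}, \code{sigma2_a},
#'   \code{sigma2_s}, \code{loglik}, \code{par_table} (estimates with 95\%
#'   Wald intervals), \code{converged}, \code{boundary}.
#' @export
fit_reml_ml <- function(data, location = ~1, scale = ~1,
                        method = c("reml", "ml"), random_study = TRUE,
                        rho_m = 0.5, V = NULL, phylo = NULL,
                        species_effect = FALSE, control = list()) {
  method <- match.arg(method)
  cl <- match.call()

  absorbed <- FALSE
  # identifiability: one effect per study + intercept-only scale part
  one_per_study <- !anyDuplicated(data$study)
  if (random_study && one_per_study && length(all.vars(scale)) == 0 &&
      is.null(phylo) && !species_effect) {
    message("one effect size per study with an intercept-only scale part: ",
            "dropping the study random effect; exp(2*beta0_s) carries the ",
            "total heterogeneity variance")
    random_study <- FALSE
    absorbed <- TRUE
  }

  aliased_phylo <- FALSE
  if (!is.null(phylo)) {
    offd <- phylo$A; diag(offd) <- 0
    if (max(abs(offd)) < 1e-12) {
      .warnf(paste("phylogenetic correlation is the identity: phylogenetic",
                   "and species variances are aliased; fitting a single",
                   "species-level variance"))
      phylo <- NULL
      species_effect <- TRUE
      aliased_phylo <- TRUE
    }
  }

  ctx <- .ls_ctx(data, location, scale, random_study = random_study,
                 rho_m = rho_m, V = V, phylo = phylo,
                 species_effect = species_effect)
  reml <- method == "reml"
  fn <- function(par) .ls_eval(par, ctx, reml = reml)

  starts <- .ls_starts(ctx, control$n_starts %||% 5L)
  rel_tol <- control$rel_tol %||% 1e-8
  best <- NULL
  for (st in starts) {
    opt <- tryCatch(
      stats::nlminb(st, fn, control = list(rel.tol = rel_tol * 1e-2,
                                           iter.max = 500L, eval.max = 2000L)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$objective)) next
    if (is.null(best) || opt$objective < best$objective - 1e-12) best <- opt
  }
  if (is.null(best)) .stopf("all optimizer starts failed")
  converged <- best$convergence == 0 && best$objective < .BIG / 2
  # high-precision polish from the winning start
  pol <- tryCatch(
    stats::nlminb(best$par, fn, control = list(rel.tol = 1e-14,
                                               x.tol = 1e-12,
                                               iter.max = 300L,
                                               eval.max = 1000L)),
    error = function(e) NULL)
  if (!is.null(pol) && is.finite(pol$objective) &&
      pol$objective <= best$objective)
    best <- pol

  det <- .ls_eval(best$par, ctx, reml = reml, details = TRUE)

  vcov_theta <- .wald_vcov_theta(best$par, fn, ctx)

  fit <- .assemble_fit(ctx, det, best, vcov_theta, method, converged,
                       absorbed, cl)
  fit$aliased_phylo <- aliased_phylo
  fit
}

# Wald covariance of (beta_s, log variance components) from the numerical
# Hessian of the objective. Log-variance coordinates whose component sits
# at the zero boundary make the surface flat; they are dropped from the
# inversion and their rows/columns reported as NA rather than poisoning
# the coefficient covariances.
.wald_vcov_theta <- function(par, fn, ctx) {
  npar <- length(par)
  keep <- rep(TRUE, npar)
  if (ctx$npar > ctx$ns) {
    vc_idx <- (ctx$ns + 1):ctx$npar
    keep[vc_idx] <- par[vc_idx] > log(1e-8)   # boundary components
  }
  inv <- function(H) {
    if (is.null(H) || !all(is.finite(H))) return(NULL)
    sub <- tryCatch(solve(H[keep, keep, drop = FALSE]),
                    error = function(e) NULL)
    if (!is.null(sub) && all(diag(sub) > 0)) sub else NULL
  }
  sub <- inv(tryCatch(stats::optimHess(par, fn), error = function(e) NULL))
  if (is.null(sub)) # more careful (Richardson) differences on hard surfaces
    sub <- inv(tryCatch(numDeriv::hessian(fn, par),
                        error = function(e) NULL))
  if (is.null(sub)) return(NULL)
  V <- matrix(NA_real_, npar, npar)
  V[keep, keep] <- sub
  V
}

# deterministic multi-start values for (beta_s, log variance components)
.ls_starts <- function(ctx, n_starts) {
  r <- stats::lm.fit(ctx$X_l, ctx$y)$residuals
  excess <- max(stats::var(r) - mean(ctx$v), 0.05 * stats::var(r), 1e-4)
  nvc <- length(ctx$vc_names)
  share <- excess / (1 + nvc)
  base <- c(0.5 * log(share), rep(0, ctx$ns - 1), rep(log(share), nvc))
  offs <- list(
    numeric(length(base)),
    c(rep(0.75, ctx$ns), rep(-1.5, nvc)),
    c(rep(-0.75, ctx$ns), rep(1.5, nvc)),
    c(1.5, rep(0, ctx$ns - 1), rep(-3, nvc)),
    c(-1.5, rep(0, ctx$ns - 1), rep(3, nvc))
  )
  offs <- offs[seq_len(min(n_starts, length(offs)))]
  lapply(offs, function(o) base + o)
}

.assemble_fit <- function(ctx, det, best, vcov_theta, method, converged,
                          absorbed, cl) {
  ns <- ctx$ns
  p <- ctx$p
  vc_names <- ctx$vc_names
  zcrit <- stats::qnorm(0.975)

  se_bs <- rep(NA_real_, ns)
  se_logvc <- stats::setNames(rep(NA_real_, length(vc_names)), vc_names)
  vcov_bs <- matrix(NA_real_, ns, ns,
                    dimnames = list(colnames(ctx$X_s), colnames(ctx$X_s)))
  if (!is.null(vcov_theta)) {
    se_all <- sqrt(pmax(diag(vcov_theta), 0))
    se_bs <- se_all[seq_len(ns)]
    if (length(vc_names)) se_logvc[] <- se_all[ns + seq_along(vc_names)]
    vcov_bs[] <- vcov_theta[seq_len(ns), seq_len(ns)]
  }

  vc <- det$vc
  boundary <- vc < 1e-8
  vc_rep <- ifelse(boundary, 0, vc)

  rows <- list()
  add <- function(name, est, se, lb, ub)
    rows[[length(rows) + 1L]] <<- data.frame(
      param = name, estimate = est, se = se, ci.lb = lb, ci.ub = ub,
      stringsAsFactors = FALSE)
  bl <- det$beta_l
  se_bl <- sqrt(diag(det$vcov_l))
  for (i in seq_len(p))
    add(paste0("location.", names(bl)[i]), bl[i], se_bl[i],
        bl[i] - zcrit * se_bl[i], bl[i] + zcrit * se_bl[i])
  bs <- det$beta_s
  for (i in seq_len(ns))
    add(paste0("scale.", names(bs)[i]), bs[i], se_bs[i],
        bs[i] - zcrit * se_bs[i], bs[i] + zcrit * se_bs[i])
  for (k in seq_along(vc_names)) {
    nm <- vc_names[k]
    if (boundary[k]) {
      add(nm, 0, NA_real_, NA_real_, NA_real_)
    } else {
      lse <- se_logvc[k]
      add(nm, vc[k], lse * vc[k],  # delta-method SE on the variance scale
          exp(log(vc[k]) - zcrit * lse), exp(log(vc[k]) + zcrit * lse))
    }
  }
  par_table <- do.call(rbind, rows)
  rownames(par_table) <- NULL

  structure(list(
    beta_l = det$beta_l, vcov_l = det$vcov_l,
    beta_s = det$beta_s, vcov_s = vcov_bs,
    sigma2_ul = if (ctx$random_study) unname(vc_rep["sigma2_ul"]) else
      if (absorbed) 0 else NA_real_,
    sigma2_a = if (ctx$use_phylo) unname(vc_rep["sigma2_a"]) else NA_real_,
    sigma2_s = if (ctx$use_phylo || ctx$use_species)
      unname(vc_rep["sigma2_s"]) else NA_real_,
    sigma2_us = NA_real_, rho_u = NA_real_,
    loglik = -best$objective, method = method,
    par_table = par_table, vcov_theta = vcov_theta,
    converged = converged, boundary = stats::setNames(boundary, vc_names),
    absorbed_study_variance = absorbed,
    theta = best$par, ctx = ctx, call = cl
  ), class = "lsmeta_fit")
}

#' @export
print.lsmeta_fit <- function(x, ...) {
  cat(sprintf("Location-scale meta-regression (%s)\n", toupper(x$method)))
  cat(sprintf("%d effect sizes, %d studies; log-likelihood %.4f\n",
              x$ctx$K, x$ctx$J, x$loglik))
  if (!x$converged) cat("** optimizer did not report convergence **\n")
  print(x$par_table, digits = 4)
  if (any(x$boundary))
    cat("variance component(s) at the zero boundary:",
        paste(names(x$boundary)[x$boundary], collapse = ", "), "\n")
  invisible(x)
}

#' Summarize a fitted location-scale model
#'
#' @param object an \code{"lsmeta_fit"}.
#' @param ... unused.
#' @return the parameter table (estimates, SEs, 95\% Wald intervals),
#'   invisibly printed.
#' @export
summary.lsmeta_fit <- function(object, ...) {
  print(object)
  invisible(object$par_table)
}

#' @export
coef.lsmeta_fit <- function(object, ...) {
  stats::setNames(object$par_table$estimate, object$par_table$param)
}

#' @export
logLik.lsmeta_fit <- function(object, ...) {
  structure(object$loglik, df = object$ctx$p + object$ctx$npar,
            class = "logLik")
}

#' Cluster-robust covariance for the location coefficients
#'
#' Study-clustered sandwich covariance for the GLS location coefficients,
#' guarding against misspecification of the dependence structure (e.g., a
#' wrong working \code{rho_m}). A small-sample adjustment
#' \eqn{J/(J-1) \times (K-1)/(K-p)} is applied. Intended to be reported
#' alongside, not instead of, the model-based covariance.
#'
#' @param fit an \code{"lsmeta_fit"} from \code{\link{fit_reml_ml}}.
#' @return the adjusted covariance matrix of the location coefficients,
#'   with attribute \code{"se"} (robust standard errors).
#' @export
cluster_robust_vcov <- function(fit) {
  stopifnot(inherits(fit, "lsmeta_fit"))
  ctx <- fit$ctx
  if (ctx$J < 2L) .stopf("cluster-robust adjustment needs at least 2 studies")
  if (ctx$J <= ctx$p)
    .warnf("fewer studies (%d) than location coefficients (%d): the robust adjustment is unreliable", ctx$J, ctx$p)
  det <- .ls_eval(fit$theta, ctx, reml = fit$method == "reml", details = TRUE)
  r <- ctx$y - drop(ctx$X_l %*% det$beta_l)

  if (ctx$fast) {
    id <- 1 / det$d
    t1 <- rowsum(ctx$X_l * (r * id), ctx$sidx)            # J x p
    if (det$tau2 > 0) {
      t2x <- rowsum(ctx$X_l * id, ctx$sidx)
      t2r <- drop(rowsum(r * id, ctx$sidx))
      gj <- t1 - (det$cj * t2r) * t2x
    } else gj <- t1
    meat <- crossprod(gj)
  } else {
    eta <- drop(ctx$X_s %*% det$beta_s)
    Sig <- ctx$V + diag(exp(2 * eta), ctx$K)
    if (det$tau2 > 0) Sig <- Sig + det$tau2 * ctx$Su
    if (ctx$use_phylo) Sig <- Sig + det$vc[["sigma2_a"]] * ctx$Aexp
    if (ctx$use_phylo || ctx$use_species)
      Sig <- Sig + det$vc[["sigma2_s"]] * ctx$Ssp
    meat <- matrix(0, ctx$p, ctx$p)
    for (j in seq_len(ctx$J)) {
      ii <- which(ctx$sidx == j)
      gi <- crossprod(ctx$X_l[ii, , drop = FALSE],
                      solve(Sig[ii, ii, drop = FALSE], r[ii]))
      meat <- meat + tcrossprod(gi)
    }
  }
  J <- ctx$J; K <- ctx$K; p <- ctx$p
  adj <- J / (J - 1) * (K - 1) / max(K - p, 1)
  Vr <- adj * det$vcov_l %*% meat %*% det$vcov_l
  dimnames(Vr) <- dimnames(det$vcov_l)
  structure(Vr, se = sqrt(diag(Vr)))
}

#' Wald test (or posterior summary) for a single coefficient
#'
#' For REML/ML fits, a two-sided z-test of \code{coefficient == null};
#' a non-zero scale-part coefficient is direct evidence of
#' heteroscedasticity. For Bayesian fits, the posterior mean, SD,
#' central 95\% interval, and the posterior tail probability of exceeding
#' the null are reported instead.
#'
#' @param fit an \code{"lsmeta_fit"} or \code{"lsmeta_bayes"} object.
#' @param coefficient parameter name as in \code{fit$par_table$param},
#'   e.g. \code{"scale.x"} or \code{"location.intrcpt"}.
#' @param null null value (default 0).
#' @return a one-row data.frame with the estimate, its uncertainty, the
#'   95\% interval and the test summary.
#' @export
wald_test <- function(fit, coefficient, null = 0) {
  pt <- fit$par_table
  row <- pt[pt$param == coefficient, , drop = FALSE]
  if (!nrow(row)) .stopf("unknown coefficient '%s'", coefficient)
  if (inherits(fit, "lsmeta_bayes")) {
    dr <- .draws_matrix(fit$draws)[, coefficient]
    p_gt <- mean(dr > null)
    out <- data.frame(param = coefficient, estimate = mean(dr),
                      sd = stats::sd(dr),
                      ci.lb = unname(stats::quantile(dr, 0.025)),
                      ci.ub = unname(stats::quantile(dr, 0.975)),
                      p_greater_than_null = p_gt,
                      stringsAsFactors = FALSE)
    return(out)
  }
  z <- (row$estimate - null) / row$se
  data.frame(param = coefficient, estimate = row$estimate, se = row$se,
             ci.lb = row$ci.lb, ci.ub = row$ci.ub, zval = z,
             pval = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
}

#' Phylogenetic multilevel location-scale fit
#'
#' Convenience wrapper around \code{\link{fit_reml_ml}} adding the
#' phylogenetic (\code{sigma2_a}, with correlation \code{A}) and
#' non-phylogenetic (\code{sigma2_s}) species-level random effects to the
#' location part; the scale part stays fixed-effects only. The ratio
#' \code{sigma2_a / (sigma2_a + sigma2_s)} is the phylogenetic
#' heritability (lambda / H^2), available through
#' \code{\link{phylo_heritability}} or \code{\link{heterogeneity}}.
#'
#' @inheritParams fit_reml_ml
#' @param phylo a \code{\link{newick_to_phylo_corr}} object (required).
#' @return an \code{"lsmeta_fit"}.
#' @export
fit_phylogenetic <- function(data, location = ~1, scale = ~1,
                             method = c("reml", "ml"), phylo,
                             random_study = TRUE, rho_m = 0.5, V = NULL,
                             control = list()) {
  if (missing(phylo) || !inherits(phylo, "phylo_corr"))
    .stopf("'phylo' must be a phylo_corr object")
  fit_reml_ml(data, location = location, scale = scale, method = method,
              random_study = random_study, rho_m = rho_m, V = V,
              phylo = phylo, species_effect = TRUE, control = control)
}
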