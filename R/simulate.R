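#' Configuration for the synthetic meta-analytic data generator
#'
#' Describes the full generative model for a multilevel location-scale
#' meta-analysis: per-study bivariate-normal random effects in the
#' location and scale parts (variances \code{sigma2_ul}, \code{sigma2_us},
#' correlation \code{rho_u}), a log-linear scale model for the residual
#' SD, optional phylogenetic/species effects on the location part, known
#' sampling variances drawn from a stated distribution, and an assumed
#' sampling correlation \code{rho_m} for shared-subject effects.
#'
#' Moderators are declared as a named list; each element is a list with a
#' \code{type}: \code{"normal"} (\code{mean}, \code{sd}),
#' \code{"uniform"} (\code{min}, \code{max}), \code{"categorical"}
#' (\code{levels}, \code{probs}), \code{"year"} (publication years,
#' uniform integers in \code{from:to}, study-level, also stored in the
#' \code{year} column), or \code{"se"} (the effect's sampling standard
#' error, for simulating small-study bias in either model part). A
#' \code{level = "study"} entry makes the draw constant within study
#' (default \code{"effect"}; \code{"year"} is always study-level).
#'
#' \code{beta_l} and \code{beta_s} are named vectors aligned to the
#' design columns generated from the moderators: \code{intrcpt} plus one
#' entry per continuous moderator or non-reference factor level (e.g.
#' \code{groupB}).
#'
#' @param n_studies number of studies.
#' @param effects_per_study a single count, or a vector of counts sampled
#'   from uniformly per study.
#' @param beta_l,beta_s named true coefficient vectors for the location
#'   part and the scale part (log residual SD scale).
#' @param sigma2_ul,sigma2_us between-study variances in the location and
#'   scale parts.
#' @param rho_u correlation of the two study effects, in [-1, 1].
#' @param sigma2_a,sigma2_s phylogenetic and species-level variances
#'   (location part); need \code{tree} and \code{n_species} when positive.
#' @param tree optional \code{\link{newick_to_phylo_corr}} object; when
#'   \code{NULL} and \code{sigma2_a > 0} a pure-birth tree is simulated.
#' @param n_species number of species (species are assigned to studies
#'   cyclically); 0 for no species structure.
#' @param moderators named list of moderator generators (see Details).
#' @param v_dist sampling-variance generator:
#'   \code{list(type = "uniform", min = 0.01, max = 0.2)} (default,
#'   right-skewed precision typical of ecological meta-analyses),
#'   \code{list(type = "fixed", values = ...)} recycled over effects.
#' @param rho_m sampling correlation used to draw correlated sampling
#'   errors for effects sharing a \code{subject_group}.
#' @param subject_groups if \code{TRUE}, all effects within a study share
#'   one subject group (so \code{rho_m} applies within studies).
#' @param seed mandatory integer seed; the same config always reproduces
#'   the same table.
#' @return an object of class \code{"sim_config"}.
#' @export
sim_config <- function(n_studies = 30, effects_per_study = 3,
                       beta_l = c(intrcpt = 0.3),
                       beta_s = c(intrcpt = log(0.2)),
                       sigma2_ul = 0.25, sigma2_us = 0, rho_u = 0,
                       sigma2_a = 0, sigma2_s = 0, tree = NULL,
                       n_species = 0, moderators = list(),
                       v_dist = list(type = "uniform", min = 0.01, max = 0.2),
                       rho_m = 0, subject_groups = FALSE, seed) {
  if (missing(seed) || !.is_number(seed)) .stopf("a numeric 'seed' is mandatory")
  beta_l <- unlist(beta_l)  # accept list input (e.g. from YAML configs)
  beta_s <- unlist(beta_s)
  if (any(c(sigma2_ul, sigma2_us, sigma2_a, sigma2_s) < 0))
    .stopf("variances must be non-negative")
  if (abs(rho_u) > 1) .stopf("rho_u must lie in [-1, 1]")
  if (rho_m < 0 || rho_m >= 1) .stopf("rho_m must lie in [0, 1)")
  if (sigma2_a > 0 && n_species <= 1)
    .stopf("phylogenetic variance needs n_species > 1")
  structure(list(n_studies = n_studies,
                 effects_per_study = effects_per_study,
                 beta_l = beta_l, beta_s = beta_s,
                 sigma2_ul = sigma2_ul, sigma2_us = sigma2_us, rho_u = rho_u,
                 sigma2_a = sigma2_a, sigma2_s = sigma2_s, tree = tree,
                 n_species = n_species, moderators = moderators,
                 v_dist = v_dist, rho_m = rho_m,
                 subject_groups = subject_groups,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a meta-analytic dataset from a location-scale model
#'
#' Draws a complete multilevel location-scale meta-analysis: study
#' effects \code{(u_l, u_s)} from the bivariate normal with correlation
#' \code{rho_u}, residuals with SD \code{exp(scale linear predictor +
#' u_s)}, sampling errors from the block covariance \code{V}, and optional
#' phylogenetic/species effects. The true latent values and parameters
#' are returned alongside the data so parameter-recovery studies can
#' compare estimates against truth.
#'
#' @param config a \code{\link{sim_config}}.
#' @return an object of class \code{"lsmeta_sim"}: list with
#'   \code{table} (an \code{\link{effect_table}}), \code{truth} (latent
#'   draws and true parameters) and \code{config}.
#' @export
simulate_meta <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, function() .simulate_meta_impl(config))
}

.simulate_meta_impl <- function(cf) {
  J <- cf$n_studies
  eps <- cf$effects_per_study
  k_j <- if (length(eps) == 1L) rep(eps, J)
         else sample(eps, J, replace = TRUE)
  K <- sum(k_j)
  study <- rep(paste0("study", seq_len(J)), k_j)
  sidx <- rep(seq_len(J), k_j)

  # sampling variances
  v <- switch(cf$v_dist$type %||% "uniform",
    uniform = stats::runif(K, cf$v_dist$min %||% 0.01, cf$v_dist$max %||% 0.2),
    fixed   = rep_len(cf$v_dist$values, K),
    # many precise effects plus a minority of small, noisy studies --
    # the typical precision profile behind funnel-type diagnostics
    mixture = {
      noisy <- stats::runif(K) < (cf$v_dist$prop_noisy %||% 0.2)
      ifelse(noisy,
             stats::runif(K, cf$v_dist$noisy_min %||% 0.15,
                          cf$v_dist$noisy_max %||% 0.4),
             stats::runif(K, cf$v_dist$precise_min %||% 0.001,
                          cf$v_dist$precise_max %||% 0.02))
    },
    .stopf("unknown v_dist type '%s'", cf$v_dist$type))

  # publication year (study-level), if declared
  year <- NULL
  df <- data.frame(study = study, stringsAsFactors = FALSE)
  X_l_cols <- list(intrcpt = rep(1, K))
  for (nm in names(cf$moderators)) {
    m <- cf$moderators[[nm]]
    at_study <- identical(m$level, "study") || identical(m$type, "year")
    ndraw <- if (at_study) J else K
    expand <- function(x) if (at_study) x[sidx] else x
    val <- switch(m$type,
      normal = expand(stats::rnorm(ndraw, m$mean %||% 0, m$sd %||% 1)),
      uniform = expand(stats::runif(ndraw, m$min %||% 0, m$max %||% 1)),
      categorical = {
        lv <- m$levels
        expand(sample(lv, ndraw, replace = TRUE,
                      prob = m$probs %||% rep(1 / length(lv), length(lv))))
      },
      year = {
        yr <- expand(sample(seq(m$from %||% 2000, m$to %||% 2020), ndraw,
                            replace = TRUE))
        year <- yr
        yr - mean(yr)  # centered year enters the linear predictors
      },
      se = sqrt(v),
      .stopf("unknown moderator type '%s'", m$type))
    df[[nm]] <- if (identical(m$type, "year")) year else val
    if (is.character(val)) {
      lv <- sort(unique(val))
      for (l in lv[-1]) X_l_cols[[paste0(nm, l)]] <- as.numeric(val == l)
    } else {
      X_l_cols[[nm]] <- if (identical(m$type, "year")) val else val
    }
  }
  X <- do.call(cbind, X_l_cols)

  pick <- function(beta, part) {
    b <- stats::setNames(rep(0, ncol(X)), colnames(X))
    bad <- setdiff(names(beta), colnames(X))
    if (length(bad))
      .stopf("%s coefficient(s) %s match no design column (have: %s)",
             part, paste(bad, collapse = ", "),
             paste(colnames(X), collapse = ", "))
    b[names(beta)] <- beta
    b
  }
  bl <- pick(cf$beta_l, "location")
  bs <- pick(cf$beta_s, "scale")
  eta_l <- drop(X %*% bl)
  eta_s <- drop(X %*% bs)

  # bivariate study effects
  sul <- sqrt(cf$sigma2_ul); sus <- sqrt(cf$sigma2_us)
  z1 <- stats::rnorm(J); z2 <- stats::rnorm(J)
  u_l <- sul * z1
  u_s <- sus * (cf$rho_u * z1 + sqrt(1 - cf$rho_u^2) * z2)

  # species / phylogenetic effects
  a_k <- s_k <- NULL
  species <- NULL
  if (cf$n_species > 0) {
    species_lab <- paste0("sp", seq_len(cf$n_species))
    species <- species_lab[(sidx - 1L) %% cf$n_species + 1L]
    tr <- cf$tree
    if (cf$sigma2_a > 0) {
      if (is.null(tr)) {
        phy <- ape::rcoal(cf$n_species, tip.label = species_lab)
        tr <- newick_to_phylo_corr(phy)
      }
      Ach <- chol(tr$A + diag(1e-10, cf$n_species))
      a_k <- sqrt(cf$sigma2_a) *
        drop(crossprod(Ach, stats::rnorm(cf$n_species)))
      names(a_k) <- tr$species
      a_k <- a_k[species_lab]
    } else a_k <- stats::setNames(rep(0, cf$n_species), species_lab)
    s_k <- stats::setNames(stats::rnorm(cf$n_species, 0, sqrt(cf$sigma2_s)),
                           species_lab)
    cf$tree <- tr
  }

  e <- stats::rnorm(K, 0, exp(eta_s + u_s[sidx]))

  # sampling errors: correlated within subject groups when requested
  subj <- NULL
  if (isTRUE(cf$subject_groups) && cf$rho_m > 0) {
    subj <- study
    m_err <- numeric(K)
    se <- sqrt(v)
    for (j in seq_len(J)) {
      ii <- which(sidx == j)
      g <- length(ii)
      R <- matrix(cf$rho_m, g, g); diag(R) <- 1
      Vb <- R * outer(se[ii], se[ii])
      m_err[ii] <- drop(crossprod(chol(Vb), stats::rnorm(g)))
    }
  } else {
    m_err <- stats::rnorm(K, 0, sqrt(v))
  }

  y <- eta_l + u_l[sidx] + e + m_err
  if (!is.null(species)) y <- y + a_k[species] + s_k[species]

  tab_df <- data.frame(yi = y, vi = v, study = study,
                       stringsAsFactors = FALSE)
  if (!is.null(species)) tab_df$species <- species
  if (!is.null(year)) tab_df$year <- year
  if (!is.null(subj)) tab_df$subject_group <- subj
  for (nm in names(cf$moderators))
    if (!identical(cf$moderators[[nm]]$type, "year"))
      tab_df[[nm]] <- df[[nm]]

  tab <- effect_table(tab_df,
                      species = if (!is.null(species)) "species",
                      year = if (!is.null(year)) "year",
                      subject_group = if (!is.null(subj)) "subject_group")

  structure(list(
    table = tab,
    truth = list(beta_l = bl, beta_s = bs, u_l = u_l, u_s = u_s,
                 a = a_k, s = s_k, e = e, m = m_err,
                 sigma2_ul = cf$sigma2_ul, sigma2_us = cf$sigma2_us,
                 rho_u = cf$rho_u, sigma2_a = cf$sigma2_a,
                 sigma2_s = cf$sigma2_s),
    config = cf), class = "lsmeta_sim")
}

#' Parameter-recovery study
#'
#' Repeatedly simulates from a configuration, refits the generating model
#' by REML/ML, and tabulates mean bias, RMSE and 95\% interval coverage
#' for each tracked parameter. Per-replicate seeds are spawned
#' deterministically from the master seed in the config. Individual fit
#' failures are recorded, not fatal.
#'
#' @param config a \code{\link{sim_config}} (its \code{seed} is the
#'   master seed).
#' @param n_reps number of replicates (>= 2).
#' @param location,scale model formulas used for refitting; defaults
#'   reconstruct intercept + all declared moderators in both parts.
#' @param method \code{"reml"} or \code{"ml"}.
#' @param params which parameters to track; any subset of the rows of the
#'   fit's parameter table plus \code{"sigma2_ul"}; default: all location
#'   and scale coefficients.
#' @return a data.frame with one row per tracked parameter: truth, mean
#'   estimate, bias, RMSE, coverage; attribute \code{"failures"} counts
#'   failed replicates.
#' @export
recovery_study <- function(config, n_reps, location = NULL, scale = NULL,
                           method = "reml", params = NULL) {
  stopifnot(inherits(config, "sim_config"), n_reps >= 2)
  forms <- .default_formulas(config)
  location <- location %||% forms$location
  scale <- scale %||% forms$scale

  res <- vector("list", n_reps)
  fails <- 0L
  for (r in seq_len(n_reps)) {
    cf <- config
    cf$seed <- (config$seed + 7919L * r) %% .Machine$integer.max
    sim <- simulate_meta(cf)
    truth <- .true_param_vector(sim)
    fit <- tryCatch(
      suppressMessages(fit_reml_ml(sim$table, location, scale,
                                   method = method, rho_m = config$rho_m)),
      error = function(e) NULL)
    if (is.null(fit)) { fails <- fails + 1L; next }
    pt <- fit$par_table
    pt$truth <- truth[pt$param]
    pt$rep <- r
    res[[r]] <- pt
  }
  all <- do.call(rbind, res)
  if (is.null(all)) .stopf("every replicate failed")
  if (!is.null(params)) all <- all[all$param %in% params, , drop = FALSE]
  all <- all[!is.na(all$truth), , drop = FALSE]

  agg <- do.call(rbind, lapply(split(all, all$param), function(d) {
    data.frame(param = d$param[1], truth = d$truth[1],
               mean_estimate = mean(d$estimate),
               bias = mean(d$estimate - d$truth),
               rmse = sqrt(mean((d$estimate - d$truth)^2)),
               coverage = mean(d$ci.lb <= d$truth & d$truth <= d$ci.ub,
                               na.rm = TRUE),
               n_reps = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  structure(agg, failures = fails, failure_rate = fails / n_reps)
}

# formulas reconstructing all declared moderators in both parts
.default_formulas <- function(config) {
  nms <- names(config$moderators)
  f <- if (length(nms))
    stats::as.formula(paste("~", paste(nms, collapse = "+")))
  else ~1
  list(location = f, scale = f)
}

# named truth vector matching par_table parameter names
.true_param_vector <- function(sim) {
  tr <- sim$truth
  out <- c(stats::setNames(tr$beta_l, paste0("location.", names(tr$beta_l))),
           stats::setNames(tr$beta_s, paste0("scale.", names(tr$beta_s))),
           sigma2_ul = tr$sigma2_ul)
  if (sim$config$sigma2_a > 0) out <- c(out, sigma2_a = tr$sigma2_a)
  if (sim$config$n_species > 0) out <- c(out, sigma2_s = tr$sigma2_s)
  out
}

#' Type-I error and power of location/scale moderator tests
#'
#' Simulates under a null and an alternative configuration and reports
#' the rejection rate of the Wald test for a chosen coefficient in each,
#' with Monte-Carlo standard errors. The two configurations should
#' differ only in the stated parameters.
#'
#' @param config_null,config_alt \code{\link{sim_config}} objects.
#' @param n_reps replicates per configuration; a length-2 vector gives
#'   separate counts for the null and the alternative.
#' @param coefficient parameter-table name to test, e.g.
#'   \code{"scale.groupB"}.
#' @param alpha test level (default 0.05).
#' @param location,scale refitting formulas (defaults as in
#'   \code{\link{recovery_study}}).
#' @return a data.frame with rejection rates and MC standard errors under
#'   the null (type-I error) and alternative (power).
#' @export
operating_characteristics <- function(config_null, config_alt, n_reps,
                                      coefficient, alpha = 0.05,
                                      location = NULL, scale = NULL) {
  n_reps <- rep_len(n_reps, 2L)
  one <- function(cfg, label, n_reps) {
    forms <- .default_formulas(cfg)
    loc <- location %||% forms$location
    sc <- scale %||% forms$scale
    rej <- logical(0)
    fails <- 0L
    for (r in seq_len(n_reps)) {
      cf <- cfg
      cf$seed <- (cfg$seed + 104729L * r) %% .Machine$integer.max
      sim <- simulate_meta(cf)
      fit <- tryCatch(
        suppressMessages(fit_reml_ml(sim$table, loc, sc, rho_m = cfg$rho_m)),
        error = function(e) NULL)
      if (is.null(fit)) { fails <- fails + 1L; next }
      wt <- tryCatch(wald_test(fit, coefficient), error = function(e) NULL)
      if (is.null(wt) || is.na(wt$pval)) { fails <- fails + 1L; next }
      rej <- c(rej, wt$pval < alpha)
    }
    p <- mean(rej)
    data.frame(scenario = label, coefficient = coefficient,
               rejection_rate = p,
               mc_se = sqrt(p * (1 - p) / length(rej)),
               n_ok = length(rej), n_failed = fails,
               stringsAsFactors = FALSE)
  }
  rbind(one(config_null, "null", n_reps[1]),
        one(config_alt, "alternative", n_reps[2]))
}
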