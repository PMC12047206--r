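# Marginal likelihood machinery for location-scale meta-regression.
#
# The marginal covariance of y is
#   Sigma = Z_u sigma2_ul Z_u' + Z_a sigma2_a A Z_a' + Z_s sigma2_s Z_s'
#           + diag(exp(2 * X_s beta_s)) + V
# with the location coefficients beta_l profiled out by GLS. When the only
# random effect is the study intercept and V is diagonal, Sigma is
# block-diagonal with rank-1 blocks and everything is computed in O(K) via
# the Woodbury identity; otherwise a dense Cholesky path is used.

.BIG <- 1e10  # objective value returned on numerical failure

# Build the fitting context: designs, V, random-effect structure, flags.
.ls_ctx <- function(table, location = ~1, scale = ~1, random_study = TRUE,
                    rho_m = 0.5, V = NULL, phylo = NULL,
                    species_effect = FALSE) {
  des <- build_designs(table, location, scale)
  tab <- des$table
  K <- nrow(tab)

  if (is.null(V)) {
    V <- build_sampling_vcov(tab, rho_m = rho_m)
  } else {
    if (!all(dim(V) == K))
      .stopf("V has order %d but the (filtered) data has %d rows", nrow(V), K)
  }
  Vm <- unclass(V)
  attributes(Vm)[c("rho_m", "blocks")] <- NULL
  off <- Vm; diag(off) <- 0
  v_diag <- diag(Vm)
  diagonal_V <- all(off == 0)

  use_phylo <- !is.null(phylo)
  if (use_phylo) {
    .check_phylo_coverage(tab, phylo)
    if (is.null(des$species)) .stopf("phylogenetic model needs a species column")
  }
  use_species <- isTRUE(species_effect)
  if ((use_phylo || use_species) && is.null(des$species))
    .stopf("species random effect needs a species column")

  ctx <- list(
    y = tab$yi, v = v_diag, X_l = des$X_l, X_s = des$X_s,
    sidx = as.integer(des$study), J = nlevels(des$study),
    K = K, p = ncol(des$X_l), ns = ncol(des$X_s),
    table = tab, study = des$study, species = des$species,
    random_study = isTRUE(random_study),
    use_phylo = use_phylo, use_species = use_species,
    V = Vm, diagonal_V = diagonal_V
  )
  ctx$fast <- diagonal_V && !use_phylo && !use_species
  # REML constant log|X'X| (metafor's convention), for comparable loglik
  ctx$ldXX <- as.numeric(determinant(crossprod(ctx$X_l))$modulus)

  if (!ctx$fast) {
    ctx$Su <- outer(ctx$sidx, ctx$sidx, "==") * 1
    if (use_phylo) {
      sp <- as.character(des$species)
      ctx$Aexp <- phylo$A[sp, sp, drop = FALSE]
    }
    if (use_phylo || use_species) {
      spf <- as.integer(des$species)
      ctx$Ssp <- outer(spf, spf, "==") * 1
    }
  }
  # parameter layout: beta_s, then log variances for active components
  comp <- c(if (ctx$random_study) "sigma2_ul",
            if (use_phylo) "sigma2_a",
            if (use_phylo || use_species) "sigma2_s")
  ctx$vc_names <- comp
  ctx$npar <- ctx$ns + length(comp)
  ctx
}

# negative log-likelihood (ML or REML); details=TRUE returns GLS pieces
.ls_eval <- function(par, ctx, reml = TRUE, details = FALSE) {
  ns <- ctx$ns
  bs <- par[seq_len(ns)]
  vc <- exp(par[-seq_len(ns)])
  names(vc) <- ctx$vc_names
  eta <- drop(ctx$X_s %*% bs)
  if (any(abs(eta) > 200)) return(.BIG)
  e2 <- exp(2 * eta)
  tau2 <- if (ctx$random_study) vc[["sigma2_ul"]] else 0
  if (!all(is.finite(c(e2, vc)))) return(.BIG)

  W <- cbind(ctx$X_l, y = ctx$y)
  p <- ctx$p
  K <- ctx$K

  if (ctx$fast) {
    d <- e2 + ctx$v
    id <- 1 / d
    s_j <- rowsum(id, ctx$sidx)
    cj <- tau2 / (1 + tau2 * s_j)
    logdet <- sum(log(d)) + sum(log1p(tau2 * s_j))
    Wd <- W * id
    G <- crossprod(W, Wd)
    if (tau2 > 0) {
      Rj <- rowsum(Wd, ctx$sidx)
      G <- G - crossprod(Rj, Rj * drop(cj))
    }
  } else {
    Sig <- ctx$V + diag(e2, K)
    if (tau2 > 0) Sig <- Sig + tau2 * ctx$Su
    if (ctx$use_phylo) Sig <- Sig + vc[["sigma2_a"]] * ctx$Aexp
    if (ctx$use_phylo || ctx$use_species)
      Sig <- Sig + vc[["sigma2_s"]] * ctx$Ssp
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(ch)) return(.BIG)
    logdet <- 2 * sum(log(diag(ch)))
    Lt <- backsolve(ch, W, transpose = TRUE)
    G <- crossprod(Lt)
  }

  Gxx <- G[seq_len(p), seq_len(p), drop = FALSE]
  Gxy <- G[seq_len(p), p + 1]
  Gyy <- G[p + 1, p + 1]
  chx <- tryCatch(chol(Gxx), error = function(e) NULL)
  if (is.null(chx)) return(.BIG)
  beta_l <- backsolve(chx, forwardsolve(t(chx), Gxy))
  quad <- Gyy - sum(Gxy * beta_l)
  if (!is.finite(quad) || quad < 0) return(.BIG)

  nll2 <- K * log(2 * pi) + logdet + quad
  if (reml)
    nll2 <- nll2 - p * log(2 * pi) + 2 * sum(log(diag(chx))) - ctx$ldXX
  nll <- 0.5 * nll2
  if (!details) return(nll)

  vcov_l <- chol2inv(chx)
  dimnames(vcov_l) <- list(colnames(ctx$X_l), colnames(ctx$X_l))
  names(beta_l) <- colnames(ctx$X_l)
  out <- list(nll = nll, beta_l = beta_l, vcov_l = vcov_l,
              beta_s = stats::setNames(bs, colnames(ctx$X_s)),
              vc = vc, tau2 = tau2)
  if (ctx$fast) {
    out$d <- d; out$cj <- drop(cj)
  }
  out
}

#' Marginal log-likelihood of a location-scale meta-regression
#'
#' Evaluates the (restricted) log-likelihood of the marginal model at
#' user-supplied scale coefficients and variance components, with the
#' location coefficients profiled out by generalized least squares. This
#' is the objective maximized by \code{\link{fit_reml_ml}}; exposing it
#' makes grid-search and algebraic cross-checks straightforward.
#'
#' @param data an \code{\link{effect_table}}.
#' @param location,scale model formulas (see \code{\link{build_designs}}).
#' @param beta_s numeric vector of scale coefficients (log residual SD
#'   scale), aligned to the scale design columns.
#' @param sigma2_ul between-study (location) variance; 0 to omit the study
#'   random effect.
#' @param sigma2_a,sigma2_s phylogenetic and species-level variances
#'   (location part); 0 to omit.
#' @param method \code{"reml"} or \code{"ml"}.
#' @param rho_m assumed sampling correlation used when \code{V} is built
#'   internally.
#' @param V optional pre-built sampling covariance
#'   (\code{\link{build_sampling_vcov}}).
#' @param phylo a \code{\link{newick_to_phylo_corr}} object, required when
#'   \code{sigma2_a > 0}.
#' @return the log-likelihood (a single number; \code{-Inf} if the
#'   parameterization is numerically invalid).
#' @export
marginal_loglik <- function(data, location = ~1, scale = ~1, beta_s,
                            sigma2_ul = 0, sigma2_a = 0, sigma2_s = 0,
                            method = c("reml", "ml"), rho_m = 0.5, V = NULL,
                            phylo = NULL) {
  method <- match.arg(method)
  if (sigma2_a > 0 && is.null(phylo))
    .stopf("sigma2_a > 0 needs a phylogenetic correlation ('phylo')")
  ctx <- .ls_ctx(data, location, scale,
                 random_study = sigma2_ul > 0, rho_m = rho_m, V = V,
                 phylo = if (sigma2_a > 0) phylo else NULL,
                 species_effect = sigma2_s > 0 && sigma2_a <= 0)
  if (length(beta_s) != ctx$ns)
    .stopf("beta_s has length %d but the scale design has %d columns",
           length(beta_s), ctx$ns)
  vcs <- c(if (sigma2_ul > 0) sigma2_ul,
           if (sigma2_a > 0) sigma2_a,
           if (sigma2_a > 0 || sigma2_s > 0) max(sigma2_s, 1e-300))
  logs <- if (length(vcs)) log(vcs) else numeric(0)
  nll <- .ls_eval(c(beta_s, logs), ctx, reml = method == "reml")
  if (nll >= .BIG) return(-Inf)
  -nll
}
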