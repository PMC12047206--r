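#' Block-diagonal sampling (co)variance matrix
#'
#' Builds the known error covariance \code{V} of the effect-size sampling
#' errors. \code{V} is block-diagonal by study; within a study, two effect
#' sizes that were computed on the same subjects (declared through the
#' \code{subject_group} column) get the covariance
#' \eqn{\rho_m \sigma_{m a} \sigma_{m b}}, while all other within-study
#' pairs are left at zero -- dependence among those is carried by the
#' study random effect, not by \code{V}. The true correlation between
#' sampling errors is rarely known, so a working value of \code{rho_m}
#' (conventionally 0.5, with 0.8 as a sensitivity value) is assumed.
#'
#' @param table an \code{\link{effect_table}}.
#' @param rho_m assumed sampling-error correlation in [0, 1).
#' @return an object of class \code{"samp_vcov"}: the dense matrix \code{V}
#'   with attributes \code{rho_m} and \code{blocks} (row indices per study).
#' @export
build_sampling_vcov <- function(table, rho_m = 0.5) {
  stopifnot(inherits(table, "effect_table"))
  if (!.is_number(rho_m) || rho_m < 0 || rho_m >= 1)
    .stopf("rho_m must lie in [0, 1)")
  v <- table$vi
  K <- length(v)
  V <- diag(v, nrow = K)
  blocks <- split(seq_len(K), factor(table$study, levels = unique(table$study)))
  sg <- table$subject_group
  if (!is.null(sg) && rho_m > 0) {
    se <- sqrt(v)
    for (idx in blocks) {
      g <- sg[idx]
      ok <- !is.na(g) & nzchar(g)
      if (!any(ok)) next
      for (lev in unique(g[ok])) {
        ii <- idx[ok & g == lev]
        if (length(ii) < 2L) next
        off <- rho_m * outer(se[ii], se[ii])
        diag(off) <- v[ii]
        V[ii, ii] <- off
        lam <- .min_eigen(off)
        if (lam < -1e-10)
          .stopf("sampling covariance block for study '%s' is not PSD", table$study[ii[1]])
      }
    }
  }
  dimnames(V) <- list(table$effect_id, table$effect_id)
  structure(V, rho_m = rho_m, blocks = blocks,
            class = c("samp_vcov", "matrix", "array"))
}

#' Typical (average) sampling variance
#'
#' The inverse-variance weighted summary
#' \deqn{\bar\sigma^2_m = \frac{(K-1)\sum w_i}{(\sum w_i)^2 - \sum w_i^2},
#'   \quad w_i = 1/v_i,}
#' used as the sampling-variance term in relative heterogeneity (I-squared)
#' statistics. It always lies between \code{min(v)} and \code{max(v)} and
#' reduces to the common value when all variances are equal.
#'
#' @param v vector of sampling variances (all > 0, length at least 2).
#' @return the typical sampling variance, a single number.
#' @export
typical_sampling_variance <- function(v) {
  v <- as.numeric(v)
  if (length(v) < 2L) .stopf("need at least 2 sampling variances")
  if (anyNA(v) || any(v <= 0)) .stopf("all sampling variances must be > 0")
  w <- 1 / v
  sw <- sum(w)
  (length(v) - 1) * sw / (sw^2 - sum(w^2))
}
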