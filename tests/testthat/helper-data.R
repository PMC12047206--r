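# shared fixture builders; everything is generated in code

# small deterministic effect table: J studies x k effects
toy_table <- function(J = 5, k = 2, seed = 101, tau2 = 0.1, sigma_e = 0.2) {
  set.seed(seed)
  v <- runif(J * k, 0.02, 0.1)
  u <- rnorm(J, 0, sqrt(tau2))
  study <- rep(paste0("s", seq_len(J)), each = k)
  y <- 0.4 + u[rep(seq_len(J), each = k)] +
    rnorm(J * k, 0, sigma_e) + rnorm(J * k, 0, sqrt(v))
  effect_table(data.frame(yi = y, vi = v, study = study))
}

# dense brute-force ML log-likelihood (independent of the package's fast
# path): explicit Sigma, GLS by solve(), dmvnorm by hand
dense_ml_loglik <- function(y, X, Sigma) {
  b <- solve(t(X) %*% solve(Sigma, X), t(X) %*% solve(Sigma, y))
  r <- y - X %*% b
  K <- length(y)
  -0.5 * (K * log(2 * pi) + determinant(Sigma)$modulus[1] +
            drop(t(r) %*% solve(Sigma, r)))
}
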