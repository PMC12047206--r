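# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# evaluate f with a locally seeded RNG stream, restoring global state after
.with_seed <- function(seed, f) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  f()
}

# symmetric positive-semi-definiteness check via smallest eigenvalue
.min_eigen <- function(M) {
  min(eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values)
}

.is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
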