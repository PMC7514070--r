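## internal helpers: seeding, multivariate-normal sampling, fingerprints

# Set the RNG deterministically when a seed is supplied; NULL leaves the
# current stream untouched so callers can manage their own state.
set_seed_if <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

# Derive `n` child seeds from one root seed without disturbing the caller's
# RNG stream. All randomness in multi-repetition experiments flows through
# this, so one root seed pins down the whole experiment.
derive_seeds <- function(root_seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(root_seed))
  sample.int(.Machine$integer.max, n)
}

# Multivariate normal draws via the eigendecomposition square root of Sigma.
# With empirical = TRUE the standard-normal matrix is column-centred, exactly
# decorrelated (SVD rotation) and rescaled to unit SD first, so the sample
# mean and covariance of the output equal mu and Sigma exactly (up to
# rounding) -- the covariance-preserving construction used for pseudo site
# signals. With empirical = FALSE ordinary draws are returned.
rmvn_eigen <- function(n, mu, Sigma, empirical = FALSE, tol = 1e-8) {
  p <- length(mu)
  stopifnot(n >= 1L, nrow(Sigma) == p, ncol(Sigma) == p)
  eS <- eigen(Sigma, symmetric = TRUE)
  ev <- eS$values
  if (any(ev < -tol * max(abs(ev)))) {
    stop("covariance matrix is not positive semi-definite (eigenvalue ",
         format(min(ev)), ")")
  }
  ev <- pmax(ev, 0)
  Z <- matrix(rnorm(n * p), nrow = n, ncol = p)
  if (empirical) {
    if (n < p + 1L) {
      stop("empirical covariance preservation needs n > number of columns")
    }
    Z <- scale(Z, center = TRUE, scale = FALSE)
    Z <- Z %*% svd(Z, nu = 0)$v
    Z <- scale(Z, center = FALSE, scale = TRUE)
  }
  X <- Z %*% t(eS$vectors %*% diag(sqrt(ev), p))
  sweep(X, 2L, mu, "+")
}

# Cheap content fingerprint for provenance bookkeeping (not cryptographic).
fingerprint <- function(x) {
  v <- as.numeric(unlist(x, use.names = FALSE))
  v <- v[is.finite(v)]
  sprintf("fp-%d-%s", length(v),
          paste(format(c(sum(v), sum(v^2), sum(v * seq_along(v))),
                       digits = 12), collapse = "-"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
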