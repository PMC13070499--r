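# Run code with a fixed RNG seed, restoring the caller's RNG state on exit.
local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Exchangeable (compound-symmetry) correlation matrix.
exch_corr <- function(n_tests, rho) {
  if (n_tests < 1) stop("n_tests must be >= 1")
  if (rho < 0 || rho >= 1)
    stop("exchangeable correlation rho must be in [0, 1); got ", rho)
  m <- matrix(rho, n_tests, n_tests)
  diag(m) <- 1
  m
}

# Accept either a scalar exchangeable rho or a full correlation matrix;
# validate symmetry, unit diagonal, positive semidefiniteness.
as_corr_matrix <- function(corr, n_tests, what = "correlation") {
  if (is.matrix(corr)) {
    if (nrow(corr) != n_tests || ncol(corr) != n_tests)
      stop(what, " matrix must be ", n_tests, "x", n_tests)
    if (max(abs(corr - t(corr))) > 1e-8) stop(what, " matrix must be symmetric")
    if (max(abs(diag(corr) - 1)) > 1e-8)
      stop(what, " matrix must have unit diagonal")
    ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stop(what, " matrix is not positive semidefinite ",
           "(minimum eigenvalue ", signif(min(ev), 3), ")")
    corr
  } else {
    exch_corr(n_tests, corr)
  }
}

# Draw n rows from N(0, R) for a correlation matrix R (unit variances).
rmvn <- function(n, R) {
  MASS::mvrnorm(n, mu = rep(0, nrow(R)), Sigma = R)
}

logit <- function(p) log(p / (1 - p))
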