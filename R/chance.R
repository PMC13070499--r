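#' Estimate the null inter-test correlation from observed z-scores
#'
#' Pairwise-complete Pearson correlations of the per-subject z-scores in one
#' session. Because pairwise-complete estimation can yield an indefinite
#' matrix, negative eigenvalues are clipped at zero and the matrix rescaled
#' to unit diagonal; when this repair occurs it is reported via a message
#' and the `"repaired"` attribute.
#'
#' @param zs a `zscore_table`.
#' @param session session to use (default baseline).
#' @param group group whose correlations are wanted (default patients).
#' @return correlation matrix (tests x tests) with attribute `repaired`.
#' @export
estimate_null_correlation <- function(zs, session = "baseline",
                                      group = "patient") {
  sub <- zs[zs$session == session & zs$group %in% group, , drop = FALSE]
  tests <- unique(sub$test_id)
  if (length(tests) < 2) stop("need at least two tests")
  ids <- sort(unique(sub$subject_id))
  wide <- sapply(tests, function(t) {
    s <- sub[sub$test_id == t, , drop = FALSE]
    s$z[match(ids, s$subject_id)]
  })
  zero_var <- apply(wide, 2, function(col) {
    v <- stats::var(col, na.rm = TRUE)
    !is.na(v) && v == 0
  })
  if (any(zero_var))
    stop("zero variance in test(s): ",
         paste(tests[zero_var], collapse = ", "))
  R <- suppressWarnings(stats::cor(wide, use = "pairwise.complete.obs"))
  R[is.na(R)] <- 0
  diag(R) <- 1
  repaired <- FALSE
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < -1e-10) {
    vals <- pmax(ev$values, 0)
    R <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    R <- stats::cov2cor(R)
    repaired <- TRUE
    message("null correlation repaired to nearest PSD matrix ",
            "(eigenvalue clipping)")
  }
  dimnames(R) <- list(tests, tests)
  attr(R, "repaired") <- repaired
  R
}

#' Monte Carlo null distribution of multivariate impairment base rates
#'
#' Simulates cohorts of healthy-by-construction subjects whose z-scores are
#' multivariate standard normal with the given inter-test correlation, and
#' records, for each replicate cohort, the proportion of subjects with at
#' least `k` scores below the impairment cutoff. This is the chance-rate
#' reference against which an observed multivariate impairment rate is
#' tested: long batteries make some impairments likely by chance alone, and
#' inter-test correlation reduces that chance rate.
#'
#' @param n_tests number of tests in the battery.
#' @param corr scalar exchangeable correlation or full correlation matrix.
#' @param cutoff impairment cutoff (default -1.645).
#' @param n_subjects subjects per simulated cohort (use the observed cohort
#'   size).
#' @param n_reps number of replicate cohorts (default 10000).
#' @param k impairment counts of interest.
#' @param seed RNG seed.
#' @return `chance_null` list: `prop` (matrix `n_reps` x `length(k)` of
#'   cohort proportions), `k`, `mean_prop`, and the spec echo.
#' @export
simulate_chance_rates <- function(n_tests, corr = 0, cutoff = -1.645,
                                  n_subjects = 100, n_reps = 10000,
                                  k = c(1, 2), seed = 1L) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  R <- as_corr_matrix(corr, n_tests, "null correlation")
  local_seed(seed, {
    prop <- matrix(NA_real_, n_reps, length(k),
                   dimnames = list(NULL, paste0("ge", k)))
    block <- max(1L, floor(2e6 / (n_subjects * n_tests)))
    done <- 0L
    while (done < n_reps) {
      nb <- min(block, n_reps - done)
      z <- rmvn(nb * n_subjects, R)
      nimp <- rowSums(z < cutoff)
      rep_id <- rep(seq_len(nb), each = n_subjects)
      for (j in seq_along(k))
        prop[done + seq_len(nb), j] <-
          tapply(nimp >= k[j], rep_id, mean)
      done <- done + nb
    }
    structure(list(prop = prop, k = k,
                   mean_prop = colMeans(prop),
                   n_tests = n_tests, cutoff = cutoff,
                   n_subjects = n_subjects, n_reps = n_reps, seed = seed),
              class = "chance_null")
  })
}

#' One-sided Monte Carlo p-value for an observed impairment rate
#'
#' `p = (1 + #(null cohort proportions >= observed)) / (n_reps + 1)` — the
#' add-one correction keeps p strictly positive, so the smallest reportable
#' value with 999 replicates is 0.001.
#'
#' @param null a `chance_null` from [simulate_chance_rates()].
#' @param observed_proportion observed proportion of subjects with >= `k`
#'   impaired scores.
#' @param k which impairment count to test (must be in `null$k`).
#' @return p-value in (0, 1].
#' @export
chance_p_value <- function(null, observed_proportion, k) {
  j <- match(k, null$k)
  if (is.na(j)) stop("k = ", k, " not present in the null result")
  (1 + sum(null$prop[, j] >= observed_proportion)) / (null$n_reps + 1)
}

#' @export
print.chance_null <- function(x, ...) {
  cat("Monte Carlo chance impairment rates:", x$n_reps, "cohorts of",
      x$n_subjects, "subjects,", x$n_tests, "tests, cutoff", x$cutoff, "\n")
  for (j in seq_along(x$k))
    cat(sprintf("  P(>= %d impaired): mean %.3f (null 2.5-97.5%%: %.3f-%.3f)\n",
                x$k[j], x$mean_prop[j],
                stats::quantile(x$prop[, j], 0.025),
                stats::quantile(x$prop[, j], 0.975)))
  invisible(x)
}
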