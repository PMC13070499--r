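# Numeric design matrix (no intercept) from a covariate data frame:
# logicals/factors become 0/1 dummies, numeric columns pass through.
design_matrix <- function(design) {
  df <- as.data.frame(design)
  for (nm in names(df)) {
    if (is.logical(df[[nm]])) df[[nm]] <- as.numeric(df[[nm]])
    if (is.character(df[[nm]])) df[[nm]] <- factor(df[[nm]])
  }
  mm <- stats::model.matrix(~ ., data = df)
  mm[, colnames(mm) != "(Intercept)", drop = FALSE]
}

#' Detect complete or quasi-complete separation
#'
#' For binary predictors, flags any zero cell in the 2x2 crosstab with the
#' outcome (the maximum-likelihood odds ratio then diverges). For
#' continuous predictors, flags perfect thresholding of the outcome. As a
#' fallback for separation only visible in combination, a quietly fitted
#' logistic model whose coefficients diverge (|coef| > 15 with fitted
#' probabilities at 0/1) flags the offending predictors.
#'
#' @param outcome logical/0-1 outcome vector.
#' @param design covariate data frame (aligned to `outcome`).
#' @return list with `separated` (logical) and `predictors` (character,
#'   offending design-matrix columns).
#' @export
detect_separation <- function(outcome, design) {
  y <- as.numeric(outcome)
  X <- design_matrix(design)
  ok <- stats::complete.cases(X) & !is.na(y)
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  flagged <- character(0)
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    ux <- unique(x)
    if (length(ux) <= 1) next
    if (length(ux) == 2) {
      tab <- table(factor(x, levels = sort(ux)), factor(y, levels = 0:1))
      if (any(tab == 0)) flagged <- c(flagged, colnames(X)[j])
    } else {
      if (max(x[y == 1]) <= min(x[y == 0]) ||
          max(x[y == 0]) <= min(x[y == 1]))
        flagged <- c(flagged, colnames(X)[j])
    }
  }
  if (!length(flagged) && length(unique(y)) == 2) {
    diverged <- FALSE
    fit <- withCallingHandlers(
      suppressWarnings(stats::glm.fit(cbind(1, X), y,
                                      family = stats::binomial())),
      warning = function(w) invokeRestart("muffleWarning"))
    probs <- fit$fitted.values
    if (any(probs < 1e-8 | probs > 1 - 1e-8)) {
      co <- fit$coefficients[-1]
      big <- which(abs(co) > 15)
      if (length(big)) {
        flagged <- colnames(X)[big]
        diverged <- TRUE
      }
    }
  }
  list(separated = length(flagged) > 0, predictors = flagged)
}

#' Univariable and multivariable logistic regression for decline outcomes
#'
#' Maximum-likelihood logistic regression (IRLS via [stats::glm()]) of a
#' binary decline outcome on clinical predictors, reporting per predictor
#' the coefficient, odds ratio, 95% Wald confidence interval
#' (`exp(coef +/- 1.96 SE)`) and Wald p-value. Missing covariates are
#' handled by listwise deletion with the model n reported. Predictors
#' causing complete or quasi-complete separation are withheld from the fit:
#' their rows carry `NA` estimates with `separation = TRUE`, mirroring the
#' "N.A." convention of clinical reporting.
#'
#' @param outcome logical/0-1 decline indicator per subject.
#' @param design covariate data frame aligned to `outcome`.
#' @param mode `"univariable"` (each predictor fitted alone) or
#'   `"multivariable"` (all predictors jointly).
#' @param outcome_label label stored in the output rows.
#' @param max_iter IRLS iteration cap.
#' @return `logistic_fit` data frame: one row per predictor with columns
#'   `outcome`, `mode`, `predictor`, `n`, `estimate`, `se`, `or`, `ci_lo`,
#'   `ci_hi`, `p`, `separation`, `converged`.
#' @export
fit_logistic <- function(outcome, design,
                         mode = c("multivariable", "univariable"),
                         outcome_label = "decline", max_iter = 50) {
  mode <- match.arg(mode)
  y <- as.numeric(outcome)
  df <- as.data.frame(design)
  if (mode == "univariable") {
    out <- do.call(rbind, lapply(names(df), function(nm)
      fit_logistic(y, df[, nm, drop = FALSE], mode = "multivariable",
                   outcome_label = outcome_label, max_iter = max_iter)))
    out$mode <- "univariable"
    class(out) <- c("logistic_fit", "data.frame")
    return(out)
  }
  X <- design_matrix(df)
  ok <- stats::complete.cases(X) & !is.na(y)
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  n <- length(y)
  if (length(unique(y)) < 2)
    stop("outcome must contain both classes after listwise deletion")
  if (n <= ncol(X) + 1)
    stop("more parameters than observations (n = ", n, ")")
  sep <- detect_separation(y, as.data.frame(X))
  keep <- setdiff(colnames(X), sep$predictors)
  row_na <- function(pred, sep_flag) data.frame(
    outcome = outcome_label, mode = mode, predictor = pred, n = n,
    estimate = NA_real_, se = NA_real_, or = NA_real_, ci_lo = NA_real_,
    ci_hi = NA_real_, p = NA_real_, separation = sep_flag, converged = NA,
    stringsAsFactors = FALSE)
  rows <- list()
  if (length(keep)) {
    dat <- data.frame(.y = y, X[, keep, drop = FALSE], check.names = FALSE)
    fit <- suppressWarnings(
      stats::glm(.y ~ ., data = dat, family = stats::binomial(),
                 control = stats::glm.control(maxit = max_iter)))
    sm <- summary(fit)$coefficients
    for (pred in keep) {
      if (!pred %in% rownames(sm)) {
        # constant or aliased column: inestimable, reported as N.A.
        rows[[pred]] <- row_na(pred, FALSE)
        next
      }
      est <- sm[pred, "Estimate"]; se <- sm[pred, "Std. Error"]
      rows[[pred]] <- data.frame(
        outcome = outcome_label, mode = mode, predictor = pred, n = n,
        estimate = est, se = se, or = exp(est),
        ci_lo = exp(est - 1.96 * se), ci_hi = exp(est + 1.96 * se),
        p = sm[pred, "Pr(>|z|)"], separation = FALSE,
        converged = fit$converged, stringsAsFactors = FALSE)
    }
  }
  for (pred in intersect(colnames(X), sep$predictors))
    rows[[pred]] <- row_na(pred, TRUE)
  out <- do.call(rbind, rows[colnames(X)[colnames(X) %in% names(rows)]])
  rownames(out) <- NULL
  class(out) <- c("logistic_fit", "data.frame")
  out
}

#' Regression diagnostics: collinearity and linearity of the logit
#'
#' Reports (i) pairwise predictor correlations with a flag above 0.7,
#' (ii) variance inflation factors from auxiliary linear regressions
#' (`VIF = 1/(1 - R^2)`, tolerance = 1/VIF) with a flag at VIF >= 5, and
#' (iii) when an outcome is supplied, Box-Tidwell linearity-of-the-logit
#' checks: the logistic model is augmented with `x * ln(x)` terms for each
#' strictly positive continuous predictor and their Wald p-values reported
#' (a small p indicates non-linearity in the logit). Continuous predictors
#' containing zeros are shifted by +0.5 before taking logs, with a warning.
#'
#' @param design covariate data frame.
#' @param outcome optional binary outcome enabling the Box-Tidwell check.
#' @param vif_flag VIF flag threshold (default 5).
#' @param corr_flag absolute correlation flag threshold (default 0.7).
#' @return list with `correlations` (data frame of pairs), `vif`
#'   (per-predictor VIF/tolerance/flag) and `box_tidwell` (per continuous
#'   predictor: shift applied and Wald p of the `x ln x` term; `NULL`
#'   without an outcome).
#' @export
model_diagnostics <- function(design, outcome = NULL, vif_flag = 5,
                              corr_flag = 0.7) {
  X <- design_matrix(design)
  X <- X[stats::complete.cases(X), , drop = FALSE]
  p <- ncol(X)
  qrX <- qr(cbind(1, X))
  if (qrX$rank < p + 1) {
    dep <- colnames(X)[setdiff(seq_len(p) + 1, qrX$pivot[seq_len(qrX$rank)]) - 1]
    stop("rank-deficient design; collinear column(s): ",
         paste(dep, collapse = ", "))
  }
  pairs <- NULL
  if (p >= 2) {
    R <- stats::cor(X)
    idx <- which(upper.tri(R), arr.ind = TRUE)
    pairs <- data.frame(pred1 = colnames(X)[idx[, 1]],
                        pred2 = colnames(X)[idx[, 2]],
                        r = R[idx],
                        flag = abs(R[idx]) > corr_flag,
                        stringsAsFactors = FALSE)
  }
  vif <- vapply(seq_len(p), function(j) {
    if (p == 1) return(1)
    r2 <- summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
    1 / (1 - r2)
  }, numeric(1))
  vif_df <- data.frame(predictor = colnames(X), vif = vif,
                       tolerance = 1 / vif, flag = vif >= vif_flag,
                       stringsAsFactors = FALSE)
  bt <- NULL
  if (!is.null(outcome)) {
    y <- as.numeric(outcome)
    okrows <- stats::complete.cases(design_matrix(design)) & !is.na(y)
    Xf <- design_matrix(design)[okrows, , drop = FALSE]
    y <- y[okrows]
    cont <- colnames(Xf)[apply(Xf, 2, function(x) length(unique(x)) > 2)]
    if (length(cont)) {
      bt_rows <- lapply(cont, function(nm) {
        x <- Xf[, nm]
        shift <- 0
        if (min(x) <= 0) {
          shift <- 0.5 - min(pmin(x, 0))
          if (min(x) == 0) shift <- 0.5
          warning("Box-Tidwell: shifting '", nm, "' by +", shift,
                  " to make it strictly positive")
          x <- x + shift
        }
        btname <- paste0(nm, "_xlnx")
        dat <- data.frame(.y = y, Xf, check.names = FALSE)
        dat[[btname]] <- x * log(x)
        fit <- suppressWarnings(
          stats::glm(.y ~ ., data = dat, family = stats::binomial()))
        sm <- summary(fit)$coefficients
        pval <- if (btname %in% rownames(sm)) sm[btname, "Pr(>|z|)"]
                else NA_real_
        data.frame(predictor = nm, shift = shift, p = pval,
                   stringsAsFactors = FALSE)
      })
      bt <- do.call(rbind, bt_rows)
    }
  }
  list(correlations = pairs, vif = vif_df, box_tidwell = bt)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value by the point-probability method: the sum of
#' hypergeometric probabilities of all tables (with the observed margins)
#' no more probable than the observed one. Degenerate tables with an empty
#' margin return p = 1.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return two-sided p-value.
#' @export
fisher_exact <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2, 2))) stop("table must be 2x2")
  if (any(m < 0) || any(m != round(m)))
    stop("counts must be non-negative integers")
  if (sum(m) == 0) return(1)
  stats::fisher.test(m)$p.value
}
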