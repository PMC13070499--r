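#' Fit the control retest regression for one test
#'
#' Ordinary least squares of follow-up z on baseline z over controls with
#' both sessions. The fitted intercept absorbs the practice effect, the
#' slope (< 1 under imperfect reliability) encodes regression to the mean,
#' and the residual SD (standard error of estimate, n-2 denominator) is the
#' reliable-change denominator.
#'
#' @param zs a `zscore_table` containing control records.
#' @param test_id which test to fit.
#' @return One-row data frame (`control_model`): `test_id`, `n_controls`,
#'   `b0`, `b1`, `see`, `x_bar`, `ss_x`, `r12`.
#' @export
fit_control_regression <- function(zs, test_id) {
  sub <- zs[zs$group == "control" & zs$test_id == test_id, , drop = FALSE]
  x1 <- sub$z[match_session(sub, "baseline")]
  y2 <- sub$z[match_session(sub, "followup")]
  ok <- !is.na(x1) & !is.na(y2)
  x1 <- x1[ok]; y2 <- y2[ok]
  n <- length(x1)
  if (n < 3)
    stop("insufficient control data for test '", test_id,
         "': need >= 3 complete pairs, have ", n)
  if (stats::sd(x1) == 0)
    stop("degenerate design for test '", test_id,
         "': all control baselines are equal")
  fit <- stats::lm(y2 ~ x1)
  see <- sqrt(sum(stats::residuals(fit)^2) / (n - 2))
  data.frame(test_id = test_id, n_controls = n,
             b0 = unname(stats::coef(fit)[1]),
             b1 = unname(stats::coef(fit)[2]),
             see = see, x_bar = mean(x1),
             ss_x = sum((x1 - mean(x1))^2),
             r12 = stats::cor(x1, y2),
             stringsAsFactors = FALSE)
}

# subjects ordered identically in both sessions of a per-test slice
match_session <- function(sub, session) {
  idx <- which(sub$session == session)
  idx[order(sub$subject_id[idx])]
}

#' Fit control retest regressions for every RCI-eligible test
#'
#' @param zs a `zscore_table` containing control records.
#' @param battery a `cog_battery`; only tests with `rci_eligible = TRUE` are
#'   fitted.
#' @return data frame of stacked [fit_control_regression()] rows, class
#'   `control_models`.
#' @export
fit_control_models <- function(zs, battery = attr(zs, "battery")) {
  eligible <- battery$test_id[battery$rci_eligible]
  out <- do.call(rbind, lapply(eligible, function(t)
    fit_control_regression(zs, t)))
  class(out) <- c("control_models", "data.frame")
  out
}

#' Write / read fitted control models as CSV
#'
#' @param models a `control_models` data frame.
#' @param path CSV path.
#' @return `read_control_models()` returns the `control_models` data frame.
#' @export
write_control_models <- function(models, path) {
  utils::write.csv(models, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_control_models
#' @export
read_control_models <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("control_models", "data.frame")
  out
}

#' Regression-based reliable change index
#'
#' `rci = (y2 - (b0 + b1 * x1)) / denominator`, the standardised deviation
#' of the observed retest score from the retest score predicted by the
#' control regression. Because the control fit absorbs practice effects and
#' regression to the mean, a patient who merely fails to show the controls'
#' practice gain receives a negative RCI. The denominator is either the
#' residual SD of the control regression (`variant = "see"`, default) or the
#' full prediction standard error
#' `see * sqrt(1 + 1/n + (x1 - x_bar)^2 / ss_x)` (`variant = "prediction"`),
#' which additionally accounts for estimation error in the control fit; the
#' two agree as the control sample grows.
#'
#' @param x1,y2 baseline and follow-up oriented z-scores (vectors).
#' @param model one row of a `control_models` data frame.
#' @param variant `"see"` or `"prediction"`.
#' @return numeric RCI values; `NA` where either score is missing.
#' @export
rci <- function(x1, y2, model, variant = c("see", "prediction")) {
  variant <- match.arg(variant)
  if (!is.finite(model$see) || model$see <= 0)
    stop("degenerate control model for test '", model$test_id,
         "' (residual SD ", model$see, "); refit on a larger or noisier ",
         "control sample before computing RCIs")
  y2_hat <- model$b0 + model$b1 * x1
  denom <- if (variant == "see") model$see else
    model$see * sqrt(1 + 1 / model$n_controls +
                       (x1 - model$x_bar)^2 / model$ss_x)
  (y2 - y2_hat) / denom
}

#' Classify a reliable change index
#'
#' Declined iff `rci < -threshold`, improved iff `rci > threshold`
#' (strict, so a value exactly at the threshold is stable), else stable.
#'
#' @param rci_value numeric RCI values.
#' @param threshold positive threshold; default 1.645 (two-tailed
#'   alpha = 0.10, i.e. 5% per tail in a calibrated null).
#' @return factor with levels declined/stable/improved (`NA` propagates).
#' @export
classify_change <- function(rci_value, threshold = 1.645) {
  if (!is.finite(threshold) || threshold <= 0)
    stop("threshold must be positive")
  out <- ifelse(rci_value < -threshold, "declined",
                ifelse(rci_value > threshold, "improved", "stable"))
  factor(out, levels = c("declined", "stable", "improved"))
}

#' Simple z-difference change criterion
#'
#' `delta_z = y2 - x1`; declined iff the drop is at least one z-score,
#' i.e. `delta_z <= -1` (boundary inclusive). This criterion ignores
#' practice effects and is kept for comparability with studies that do not
#' use RCIs.
#'
#' @param x1,y2 baseline and follow-up oriented z-scores.
#' @param threshold magnitude of drop that counts as decline (default 1).
#' @return data frame `delta_z`, `deltaz_class` (declined/stable; `NA`
#'   where a score is missing).
#' @export
delta_z_classify <- function(x1, y2, threshold = 1) {
  dz <- y2 - x1
  cls <- ifelse(dz <= -threshold, "declined", "stable")
  data.frame(delta_z = dz,
             deltaz_class = factor(cls, levels = c("declined", "stable")))
}

#' Per-subject per-test change results for a patient cohort
#'
#' Computes, for every patient and battery test, the baseline/follow-up
#' z-scores, the predicted retest score, the RCI (RCI-eligible tests only)
#' with its three-way classification, and the delta-z criterion.
#'
#' @param zs a `zscore_table` containing patient records.
#' @param models `control_models` from [fit_control_models()].
#' @param battery a `cog_battery`.
#' @param variant RCI denominator variant (see [rci()]).
#' @param threshold RCI classification threshold.
#' @param group which group to evaluate (default patients).
#' @return data frame (`change_results`): `subject_id`, `test_id`, `x1`,
#'   `y2`, `y2_hat`, `rci`, `rci_class`, `delta_z`, `deltaz_class`.
#' @export
compute_change <- function(zs, models, battery = attr(zs, "battery"),
                           variant = "see", threshold = 1.645,
                           group = "patient") {
  out <- do.call(rbind, lapply(battery$test_id, function(tid) {
    sub <- zs[zs$group %in% group & zs$test_id == tid, , drop = FALSE]
    ids <- sort(unique(sub$subject_id))
    x1 <- sub$z[match(paste(ids, "baseline"),
                      paste(sub$subject_id, sub$session))]
    y2 <- sub$z[match(paste(ids, "followup"),
                      paste(sub$subject_id, sub$session))]
    res <- data.frame(subject_id = ids, test_id = tid, x1 = x1, y2 = y2,
                      y2_hat = NA_real_, rci = NA_real_,
                      stringsAsFactors = FALSE)
    m <- models[models$test_id == tid, , drop = FALSE]
    if (nrow(m) == 1) {
      res$y2_hat <- m$b0 + m$b1 * x1
      res$rci <- rci(x1, y2, m, variant)
    }
    dz <- delta_z_classify(x1, y2)
    res$rci_class <- classify_change(res$rci, threshold)
    res$delta_z <- dz$delta_z
    res$deltaz_class <- dz$deltaz_class
    res
  }))
  rownames(out) <- NULL
  attr(out, "battery") <- battery
  attr(out, "threshold") <- threshold
  class(out) <- c("change_results", "data.frame")
  out
}

#' Domain-level change from average RCIs
#'
#' Averages each subject's available per-test RCIs within each cognitive
#' domain (unweighted; RCI-eligible tests only) and classifies the average
#' with the same threshold used per test. Domains with fewer than
#' `min_tests` available RCIs are reported as missing.
#'
#' @param change a `change_results` data frame from [compute_change()].
#' @param battery a `cog_battery`.
#' @param min_tests minimum number of contributing tests per domain.
#' @param threshold classification threshold.
#' @return data frame: `subject_id`, `domain`, `mean_rci`, `n_tests_used`,
#'   `class`.
#' @export
domain_change <- function(change, battery = attr(change, "battery"),
                          min_tests = 1,
                          threshold = attr(change, "threshold") %||% 1.645) {
  eligible <- battery$test_id[battery$rci_eligible]
  sub <- change[change$test_id %in% eligible, , drop = FALSE]
  sub$domain <- battery$domain[match(sub$test_id, battery$test_id)]
  ids <- sort(unique(change$subject_id))
  grid <- expand.grid(subject_id = ids, domain = unique(battery$domain),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(sub$subject_id, sub$domain)
  grid$mean_rci <- NA_real_
  grid$n_tests_used <- 0L
  agg_n <- tapply(!is.na(sub$rci), key, sum)
  agg_m <- tapply(sub$rci, key, mean, na.rm = TRUE)
  gk <- paste(grid$subject_id, grid$domain)
  hit <- match(gk, names(agg_n))
  grid$n_tests_used[!is.na(hit)] <- as.integer(agg_n[hit[!is.na(hit)]])
  grid$mean_rci[!is.na(hit)] <- as.numeric(agg_m[hit[!is.na(hit)]])
  grid$mean_rci[grid$n_tests_used < min_tests] <- NA_real_
  grid$class <- classify_change(grid$mean_rci, threshold)
  grid[order(grid$subject_id, grid$domain), , drop = FALSE]
}

#' Cohort-level change summary and test selection
#'
#' Per-test and per-domain proportions of subjects declined/improved (over
#' subjects with an available result), plus the list of tests whose RCI
#' decline proportion strictly exceeds `select_threshold` — the selection
#' rule feeding the decline prediction models.
#'
#' @param change a `change_results` data frame.
#' @param battery a `cog_battery`.
#' @param select_threshold strict selection cut on the per-test declined
#'   proportion (default 0.20).
#' @param min_tests passed to [domain_change()].
#' @return list with `by_test`, `by_domain` (data frames with `n`,
#'   `prop_declined`, `prop_improved`) and `selected_tests` (character).
#' @export
cohort_change_summary <- function(change, battery = attr(change, "battery"),
                                  select_threshold = 0.20, min_tests = 1) {
  prop_tbl <- function(cls, by) {
    ok <- !is.na(cls)
    n <- tapply(ok, by, sum)
    dec <- tapply(cls == "declined" & ok, by, sum, na.rm = TRUE)
    imp <- tapply(cls == "improved" & ok, by, sum, na.rm = TRUE)
    data.frame(id = names(n), n = as.integer(n),
               prop_declined = ifelse(n > 0, dec / n, NA_real_),
               prop_improved = ifelse(n > 0, imp / n, NA_real_),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  by_test <- prop_tbl(change$rci_class, change$test_id)
  names(by_test)[1] <- "test_id"
  by_test <- by_test[match(battery$test_id, by_test$test_id), , drop = FALSE]
  by_test <- by_test[!is.na(by_test$test_id), , drop = FALSE]
  rownames(by_test) <- NULL
  dom <- domain_change(change, battery, min_tests = min_tests)
  by_domain <- prop_tbl(dom$class, dom$domain)
  names(by_domain)[1] <- "domain"
  sel <- by_test$test_id[!is.na(by_test$prop_declined) &
                           by_test$prop_declined > select_threshold]
  list(by_test = by_test, by_domain = by_domain, selected_tests = sel)
}
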