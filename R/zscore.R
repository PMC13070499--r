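#' Standardise raw scores against normative data
#'
#' `z = (raw - norm_mean) / norm_sd`, multiplied by -1 for `lower_better`
#' tests (timed tests) so that after transformation higher z is always
#' better. Missing raw scores propagate to missing z.
#'
#' @param raw numeric vector of raw scores.
#' @param norm_mean,norm_sd normative mean and SD in raw-score units
#'   (`norm_sd > 0`).
#' @param polarity `"higher_better"` or `"lower_better"`.
#' @return numeric vector of oriented z-scores.
#' @export
#' @examples
#' z_transform(45, 50, 10, "higher_better")  # -0.5
#' z_transform(80, 60, 10, "lower_better")   # -2: slower than the norm
z_transform <- function(raw, norm_mean, norm_sd, polarity = "higher_better") {
  if (any(!is.finite(norm_sd)) || any(norm_sd <= 0))
    stop("norm_sd must be > 0")
  if (!all(polarity %in% c("higher_better", "lower_better")))
    stop("polarity must be higher_better or lower_better")
  sgn <- ifelse(polarity == "lower_better", -1, 1)
  sgn * (raw - norm_mean) / norm_sd
}

#' Z-score a whole cohort against its battery norms
#'
#' Applies [z_transform()] per test using the battery's norms, orienting all
#' scores so that higher z is better. If the battery carries stratified
#' norms (see [load_battery()]) and a covariate table is supplied, each
#' subject is scored against the first stratum whose predicate matches,
#' falling back to the default norms.
#'
#' @param cohort a `cog_cohort` of raw scores.
#' @param covariates optional per-subject covariate data frame (must contain
#'   `subject_id`) used to resolve stratified norms.
#' @return A long data frame `subject_id`, `group`, `session`, `test_id`,
#'   `z`, with class `zscore_table` and the battery attached.
#' @export
z_score_cohort <- function(cohort, covariates = NULL) {
  battery <- attr(cohort, "battery")
  strata <- attr(battery, "strata")
  long <- cohort_long(cohort)
  bi <- match(long$test_id, battery$test_id)
  mean_i <- battery$norm_mean[bi]
  sd_i <- battery$norm_sd[bi]
  if (!is.null(strata) && !is.null(covariates)) {
    ci <- match(long$subject_id, covariates$subject_id)
    for (r in seq_len(nrow(strata))) {
      rows <- which(long$test_id == strata$test_id[r] & !is.na(ci))
      if (!length(rows)) next
      hit <- rep(FALSE, length(rows))
      ok <- try(eval(parse(text = strata$when[r]),
                     covariates[ci[rows], , drop = FALSE]), silent = TRUE)
      if (!inherits(ok, "try-error")) hit <- isTRUE(ok) | (is.logical(ok) & ok)
      hit[is.na(hit)] <- FALSE
      mean_i[rows[hit]] <- strata$norm_mean[r]
      sd_i[rows[hit]] <- strata$norm_sd[r]
    }
  }
  long$z <- z_transform(long$score, mean_i, sd_i, battery$polarity[bi])
  long$score <- NULL
  attr(long, "battery") <- battery
  class(long) <- c("zscore_table", "data.frame")
  long
}

#' Classify impairment from an oriented z-score
#'
#' A score is impaired iff `z < cutoff` (strict: a score exactly at the
#' cutoff is intact). Missing z returns `NA` so the score counts neither as
#' impaired nor as intact.
#'
#' @param z oriented z-score(s).
#' @param cutoff negative z cutoff; default -1.645 (the 5th percentile of
#'   the standard normal); -1.5 is the common secondary choice.
#' @return logical vector.
#' @export
classify_impairment <- function(z, cutoff = -1.645) {
  if (!is.finite(cutoff) || cutoff >= 0) stop("cutoff must be negative")
  z < cutoff
}

#' Multivariate impairment base rates
#'
#' For one session, counts each subject's impaired scores over the tests
#' available to them (no imputation) and reports, for each `k`, the
#' proportion of subjects with at least `k` impaired scores. Only subjects
#' with at least one available test contribute.
#'
#' @param zs a `zscore_table` (see [z_score_cohort()]).
#' @param session `"baseline"` or `"followup"`.
#' @param cutoff impairment cutoff passed to [classify_impairment()].
#' @param k integer vector of impairment counts to report.
#' @param group which cohort group to evaluate (default `"patient"`).
#' @return list with `rates` (data frame `k`, `proportion`, `n_subjects`)
#'   and `profiles` (per-subject `n_tests_available`, `n_impaired`).
#' @export
impairment_base_rates <- function(zs, session = "baseline", cutoff = -1.645,
                                  k = c(1, 2), group = "patient") {
  sub <- zs[zs$session == session & zs$group %in% group, , drop = FALSE]
  if (!nrow(sub)) stop("no records for session '", session, "'")
  imp <- classify_impairment(sub$z, cutoff)
  avail <- tapply(!is.na(sub$z), sub$subject_id, sum)
  nimp <- tapply(imp, sub$subject_id, function(x) sum(x, na.rm = TRUE))
  keep <- avail >= 1
  if (!any(keep)) stop("no subject has any available test in session '",
                       session, "'")
  profiles <- data.frame(subject_id = names(avail)[keep],
                         session = session,
                         n_tests_available = as.integer(avail[keep]),
                         n_impaired = as.integer(nimp[keep]),
                         cutoff = cutoff,
                         stringsAsFactors = FALSE)
  rates <- data.frame(k = k,
                      proportion = vapply(k, function(kk)
                        mean(profiles$n_impaired >= kk), numeric(1)),
                      n_subjects = nrow(profiles))
  list(rates = rates, profiles = profiles)
}
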