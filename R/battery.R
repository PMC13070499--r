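#' @keywords internal
"_PACKAGE"

# Closed set of cognitive domains used throughout the pipeline.
COG_DOMAINS <- c("learning_memory", "visuospatial_perceptual", "language",
                 "executive", "speed_attention")

SESSIONS <- c("baseline", "followup")
GROUPS <- c("patient", "control")

#' Default 17-test neuropsychological battery
#'
#' Returns the battery used throughout the package examples: 17 test
#' variables partitioned into five cognitive domains (learning/memory,
#' visuospatial/perceptual, language, executive, speed/attention). Timed
#' tests (Trail Making, colour-word interference) are declared
#' `lower_better`; the Rey Complex Figure copy is not eligible for
#' regression-based reliable change indices. The normative means and SDs
#' shipped here are synthetic illustrative values in plausible raw-score
#' units; substitute the published norms that apply to your population via
#' [load_battery()].
#'
#' @return A `cog_battery` data frame with one row per test and columns
#'   `test_id`, `display_name`, `domain`, `subdomain`, `polarity`,
#'   `rci_eligible`, `norm_mean`, `norm_sd`.
#' @export
#' @examples
#' b <- default_battery()
#' table(b$domain)
default_battery <- function() {
  tests <- data.frame(
    test_id = c("bvmt_learning", "bvmt_recall", "ravlt_learning",
                "ravlt_recall", "tmt_a", "rey_cft_copy", "bnt",
                "phonemic_fluency", "semantic_fluency", "cwit1", "cwit2",
                "cwit3", "cwit4", "tmt_b", "digit_span_backward",
                "digit_span_forward", "coding"),
    display_name = c("BVMT-R Learning", "BVMT-R Delayed Recall",
                     "RAVLT Learning", "RAVLT Delayed Recall",
                     "Trail Making Test A", "Rey CFT copy",
                     "Boston Naming Test", "Phonemic fluency",
                     "Semantic fluency", "CWIT 1", "CWIT 2", "CWIT 3",
                     "CWIT 4", "Trail Making Test B",
                     "Digit span backward", "Digit span forward", "Coding"),
    domain = c(rep("learning_memory", 4),
               rep("visuospatial_perceptual", 2),
               rep("language", 5),
               rep("executive", 4),
               rep("speed_attention", 2)),
    subdomain = c("visuospatial", "visuospatial", "verbal", "verbal",
                  "speed", "executive",
                  "visuoperceptual", "executive", "speed", "speed", "speed",
                  "language", "language", "visuospatial", "attention",
                  "attention", "speed"),
    polarity = c("higher_better", "higher_better", "higher_better",
                 "higher_better", "lower_better", "higher_better",
                 "higher_better", "higher_better", "higher_better",
                 "lower_better", "lower_better", "lower_better",
                 "lower_better", "lower_better", "higher_better",
                 "higher_better", "higher_better"),
    rci_eligible = TRUE,
    # synthetic illustrative norms (raw-score units): counts for accuracy
    # tests, seconds for timed tests
    norm_mean = c(25, 9.5, 50, 10.5, 30, 33, 54, 40, 22, 30, 22, 50, 55,
                  70, 8, 10, 65),
    norm_sd = c(5, 2, 9, 3, 10, 3, 3.5, 11, 5, 5, 4, 10, 12, 25, 2, 2, 13),
    stringsAsFactors = FALSE
  )
  tests$rci_eligible[tests$test_id == "rey_cft_copy"] <- FALSE
  new_battery(tests)
}

new_battery <- function(tests) {
  validate_battery(tests)
  class(tests) <- c("cog_battery", "data.frame")
  tests
}

validate_battery <- function(tests) {
  required <- c("test_id", "display_name", "domain", "subdomain", "polarity",
                "rci_eligible", "norm_mean", "norm_sd")
  missing <- setdiff(required, names(tests))
  if (length(missing))
    stop("battery is missing required fields: ", paste(missing, collapse = ", "))
  dup <- tests$test_id[duplicated(tests$test_id)]
  if (length(dup))
    stop("duplicate test_id in battery: ", paste(unique(dup), collapse = ", "))
  bad <- !tests$domain %in% COG_DOMAINS
  if (any(bad))
    stop("unknown domain for test(s) ",
         paste(tests$test_id[bad], collapse = ", "), ": ",
         paste(unique(tests$domain[bad]), collapse = ", "),
         " (must be one of ", paste(COG_DOMAINS, collapse = ", "), ")")
  badp <- !tests$polarity %in% c("higher_better", "lower_better")
  if (any(badp))
    stop("unknown polarity for test(s): ",
         paste(tests$test_id[badp], collapse = ", "))
  if (any(!is.finite(tests$norm_sd) | tests$norm_sd <= 0))
    stop("norm_sd must be > 0 for all tests; offending: ",
         paste(tests$test_id[!is.finite(tests$norm_sd) | tests$norm_sd <= 0],
               collapse = ", "))
  invisible(tests)
}

#' Load a test battery (with norms) from a YAML or JSON config file
#'
#' The config holds one entry per test with the fields of
#' [default_battery()]. Optional age-/education-stratified norms can be
#' supplied per test as a `strata` list whose entries carry a `when`
#' predicate (an R expression over covariate columns, e.g. `"age_years >= 50"`)
#' plus `norm_mean`/`norm_sd`; these are attached as the `"strata"`
#' attribute and used by [z_score_cohort()] when covariates are provided.
#'
#' @param path path to a `.yaml`/`.yml` (or `.json`) battery file.
#' @return A validated `cog_battery` data frame.
#' @export
load_battery <- function(path) {
  if (!file.exists(path)) stop("battery file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("jsonlite is required to read JSON battery files")
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(cfg$tests)) cfg <- cfg$tests
  if (!length(cfg)) stop("battery file contains no tests: ", path)
  row1 <- function(t) {
    need <- c("test_id", "domain", "polarity", "norm_mean", "norm_sd")
    miss <- setdiff(need, names(t))
    if (length(miss))
      stop("battery entry ", t$test_id %||% "<unnamed>",
           " is missing fields: ", paste(miss, collapse = ", "))
    data.frame(test_id = t$test_id,
               display_name = t$display_name %||% t$test_id,
               domain = t$domain,
               subdomain = t$subdomain %||% "",
               polarity = t$polarity,
               rci_eligible = isTRUE(t$rci_eligible %||% TRUE),
               norm_mean = as.numeric(t$norm_mean),
               norm_sd = as.numeric(t$norm_sd),
               stringsAsFactors = FALSE)
  }
  tests <- do.call(rbind, lapply(cfg, row1))
  strata <- do.call(rbind, lapply(cfg, function(t) {
    if (is.null(t$strata)) return(NULL)
    do.call(rbind, lapply(t$strata, function(s) {
      data.frame(test_id = t$test_id, when = s$when,
                 norm_mean = as.numeric(s$norm_mean),
                 norm_sd = as.numeric(s$norm_sd),
                 stringsAsFactors = FALSE)
    }))
  }))
  bat <- new_battery(tests)
  if (!is.null(strata)) {
    if (any(!is.finite(strata$norm_sd) | strata$norm_sd <= 0))
      stop("stratified norm_sd must be > 0")
    attr(bat, "strata") <- strata
  }
  bat
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a two-session cohort table from CSV
#'
#' Expects a wide CSV with columns `subject_id`, `group`
#' (`patient`/`control`), `session` (`baseline`/`followup`) and one raw-score
#' column per battery test. Blank cells are kept as missing values, never
#' coerced to zero.
#'
#' @param path CSV path.
#' @param battery a `cog_battery`; score columns must be a subset of its
#'   test ids.
#' @return A `cog_cohort`: a wide data frame of raw scores with the battery
#'   attached as an attribute.
#' @export
read_cohort <- function(path, battery) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        na.strings = "")
  new_cohort(df, battery)
}

#' Construct and validate a cohort table
#'
#' @param df data frame with `subject_id`, `group`, `session` and score
#'   columns named by battery test ids.
#' @param battery a `cog_battery`.
#' @return A validated `cog_cohort`.
#' @export
new_cohort <- function(df, battery) {
  id_cols <- c("subject_id", "group", "session")
  miss <- setdiff(id_cols, names(df))
  if (length(miss))
    stop("cohort is missing required columns: ", paste(miss, collapse = ", "))
  score_cols <- setdiff(names(df), id_cols)
  unknown <- setdiff(score_cols, battery$test_id)
  if (length(unknown))
    stop("score column(s) not in battery: ", paste(unknown, collapse = ", "))
  badg <- !df$group %in% GROUPS
  if (any(badg))
    stop("unknown group value(s): ",
         paste(unique(df$group[badg]), collapse = ", "),
         " (must be patient or control)")
  bads <- !df$session %in% SESSIONS
  if (any(bads))
    stop("unknown session value(s): ",
         paste(unique(df$session[bads]), collapse = ", "),
         " (must be baseline or followup)")
  key <- paste(df$subject_id, df$session)
  if (anyDuplicated(key))
    stop("duplicate (subject_id, session) row(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  ngroup <- tapply(df$group, df$subject_id, function(g) length(unique(g)))
  if (any(ngroup > 1))
    stop("subject(s) appear in more than one group: ",
         paste(names(ngroup)[ngroup > 1], collapse = ", "))
  for (tc in score_cols) df[[tc]] <- as.numeric(df[[tc]])
  df$subject_id <- as.character(df$subject_id)
  attr(df, "battery") <- battery
  class(df) <- c("cog_cohort", "data.frame")
  df
}

#' Write a cohort table to CSV
#'
#' Rows are ordered by `subject_id` then session (baseline before followup)
#' and score columns follow battery order, so repeated writes of the same
#' cohort are byte-identical. Missing scores become blank fields.
#'
#' @param cohort a `cog_cohort`.
#' @param path output CSV path.
#' @export
write_cohort <- function(cohort, path) {
  battery <- attr(cohort, "battery")
  score_cols <- intersect(battery$test_id, names(cohort))
  ord <- order(cohort$subject_id, match(cohort$session, SESSIONS))
  out <- cohort[ord, c("subject_id", "group", "session", score_cols),
                drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @export
print.cog_battery <- function(x, ...) {
  cat("Neuropsychological battery:", nrow(x), "tests,",
      length(unique(x$domain)), "domains\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' @export
print.cog_cohort <- function(x, ...) {
  cat("Cohort table:", length(unique(x$subject_id)), "subjects (",
      sum(x$group == "patient" & x$session == "baseline"), "patients,",
      sum(x$group == "control" & x$session == "baseline"), "controls ),",
      nrow(x), "rows\n")
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

# long view of a cohort's scores: subject_id, group, session, test_id, score
cohort_long <- function(cohort) {
  battery <- attr(cohort, "battery")
  score_cols <- intersect(battery$test_id, names(cohort))
  out <- do.call(rbind, lapply(score_cols, function(tc) {
    data.frame(subject_id = cohort$subject_id, group = cohort$group,
               session = cohort$session, test_id = tc,
               score = cohort[[tc]], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
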