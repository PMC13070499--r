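#' Paired within-subject change test with a normality gate
#'
#' Tests within-subject score change between sessions. Difference scores
#' are first screened with a Kolmogorov-Smirnov test against a normal
#' distribution with the sample mean and SD; if normality is not rejected
#' (p >= 0.05) a two-tailed paired t-test is used, otherwise a two-tailed
#' Wilcoxon matched-pairs signed-rank test (normal approximation, zero
#' differences dropped). Note the KS test with estimated parameters is
#' anticonservative as a normality screen; it is used here as the
#' conventional gate in this reporting style.
#'
#' @param x1,y2 paired baseline and follow-up scores.
#' @param alpha normality gate level (default 0.05).
#' @return one-row data frame: `n`, `normality_p`, `method`, `statistic`,
#'   `p_value`, `note`.
#' @export
paired_change_test <- function(x1, y2, alpha = 0.05) {
  ok <- !is.na(x1) & !is.na(y2)
  d <- y2[ok] - x1[ok]
  n <- length(d)
  if (n < 5) stop("need at least 5 complete pairs, have ", n)
  if (all(d == 0))
    return(data.frame(n = n, normality_p = NA_real_, method = "degenerate",
                      statistic = NA_real_, p_value = 1,
                      note = "all differences zero",
                      stringsAsFactors = FALSE))
  ks <- suppressWarnings(
    stats::ks.test(d, "pnorm", mean(d), stats::sd(d)))
  if (ks$p.value >= alpha) {
    tt <- stats::t.test(y2[ok], x1[ok], paired = TRUE)
    data.frame(n = n, normality_p = ks$p.value, method = "paired_t",
               statistic = unname(tt$statistic), p_value = tt$p.value,
               note = "", stringsAsFactors = FALSE)
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(y2[ok], x1[ok], paired = TRUE, exact = FALSE,
                         correct = TRUE))
    data.frame(n = n, normality_p = ks$p.value, method = "wilcoxon",
               statistic = unname(wt$statistic), p_value = wt$p.value,
               note = "", stringsAsFactors = FALSE)
  }
}

# Per-test summary table: n pairs, mean (SD) z per session, paired change
# test, % impaired per session, and Fisher exact on the two proportions.
summarize_battery <- function(zs, battery = attr(zs, "battery"),
                              cutoff = -1.645, group = "patient") {
  rows <- lapply(battery$test_id, function(tid) {
    sub <- zs[zs$group %in% group & zs$test_id == tid, , drop = FALSE]
    ids <- sort(unique(sub$subject_id))
    x1 <- sub$z[match(paste(ids, "baseline"),
                      paste(sub$subject_id, sub$session))]
    y2 <- sub$z[match(paste(ids, "followup"),
                      paste(sub$subject_id, sub$session))]
    ok <- !is.na(x1) & !is.na(y2)
    n <- sum(ok)
    pt <- if (n >= 5) paired_change_test(x1[ok], y2[ok]) else
      data.frame(method = NA_character_, p_value = NA_real_)
    imp1 <- classify_impairment(x1[ok], cutoff)
    imp2 <- classify_impairment(y2[ok], cutoff)
    fp <- if (n > 0)
      fisher_exact(matrix(c(sum(imp1), n - sum(imp1),
                            sum(imp2), n - sum(imp2)), 2, byrow = TRUE))
      else NA_real_
    data.frame(test_id = tid,
               domain = battery$domain[battery$test_id == tid],
               n = n,
               mean_pre = mean(x1[ok]), sd_pre = stats::sd(x1[ok]),
               mean_post = mean(y2[ok]), sd_post = stats::sd(y2[ok]),
               change_method = pt$method, change_p = pt$p_value,
               pct_impaired_pre = 100 * mean(imp1),
               pct_impaired_post = 100 * mean(imp2),
               impaired_fisher_p = fp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a self-contained synthetic demo study on disk
#'
#' Writes a battery config, control and patient cohort CSVs, a covariate
#' CSV, the true decline labels, and a ready-to-run pipeline config into
#' `outdir`. Defaults produce 127 patients and 88 controls with two
#' sessions each.
#'
#' @param cfg a [sim_config()].
#' @param outdir output directory.
#' @param force overwrite an existing non-empty directory.
#' @param masks also write synthetic tumour masks (NIfTI) keyed to the
#'   subjects' decline status on the first selected test.
#' @return invisibly, a named list of the files written.
#' @export
make_demo <- function(cfg = sim_config(), outdir, force = FALSE,
                      masks = FALSE) {
  if (dir.exists(outdir) && length(dir(outdir)) && !force)
    stop("output directory ", outdir, " exists and is not empty; ",
         "use force = TRUE to overwrite")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  controls <- simulate_controls(cfg, seed = cfg$seed)
  pats <- simulate_patients(cfg, seed = cfg$seed + 1L)
  paths <- list(
    battery = file.path(outdir, "battery.yaml"),
    controls = file.path(outdir, "controls.csv"),
    patients = file.path(outdir, "patients.csv"),
    covariates = file.path(outdir, "covariates.csv"),
    truth = file.path(outdir, "truth.csv"),
    config = file.path(outdir, "pipeline.yaml"))
  write_battery_yaml(cfg$battery, paths$battery)
  write_cohort(controls, paths$controls)
  write_cohort(pats$cohort, paths$patients)
  utils::write.csv(pats$covariates, paths$covariates, row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(pats$truth, paths$truth, row.names = FALSE, quote = FALSE)
  pipeline_cfg <- list(battery = paths$battery, controls = paths$controls,
                       patients = paths$patients,
                       covariates = paths$covariates,
                       impairment_cutoffs = c(-1.645, -1.5),
                       rci_threshold = 1.645, deltaz_threshold = 1,
                       select_threshold = 0.20, rci_variant = "see",
                       chance_n_reps = 1000, seed = cfg$seed,
                       outdir = file.path(outdir, "results"))
  yaml::write_yaml(pipeline_cfg, paths$config)
  if (masks) {
    mdir <- file.path(outdir, "masks")
    dir.create(mdir, showWarnings = FALSE)
    n_masked <- min(cfg$n_patients, 20L)
    ms <- simulate_masks(n_per_group = c(ceiling(n_masked / 2),
                                         floor(n_masked / 2)),
                         seed = cfg$seed + 2L)
    # masks belong to the first patients so they join the change results
    ids <- sprintf("pat%03d", seq_len(n_masked))
    for (i in seq_along(ids))
      RNifti::writeNifti(RNifti::asNifti(ms$masks[[i]]),
                         file.path(mdir, paste0(ids[i], ".nii.gz")))
    paths$masks <- mdir
    pipeline_cfg$masks <- mdir
    yaml::write_yaml(pipeline_cfg, paths$config)
  }
  invisible(paths)
}

write_battery_yaml <- function(battery, path) {
  tests <- lapply(seq_len(nrow(battery)), function(i) as.list(battery[i, ]))
  yaml::write_yaml(list(tests = tests), path)
  invisible(path)
}

#' Run the full cognitive-change pipeline
#'
#' Sequences every stage on files referenced by a config (a YAML path or an
#' equivalent list): z-scoring, the per-test summary table with paired
#' change tests and impairment proportions, multivariate impairment base
#' rates at both cutoffs with the Monte Carlo chance test, control retest
#' regressions, per-subject reliable change and delta-z results, domain
#' averages, the >20% test selection, univariable and multivariable
#' logistic decline models with diagnostics, and (when masks are provided)
#' declined-versus-intact overlap maps. All outputs are CSV (plus NIfTI for
#' maps) under `cfg$outdir`, with a YAML run manifest carrying the seed and
#' a hash of the config. The run is deterministic given (config, seed):
#' each stochastic stage uses a named substream derived from the master
#' seed.
#'
#' @param cfg YAML path or list; see [make_demo()] for the fields.
#' @return invisibly, a list with the main in-memory results and output
#'   paths.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  seed <- as.integer(cfg$seed %||% 1L)
  outdir <- cfg$outdir %||% "cogchange_results"
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, name) {
    p <- file.path(outdir, name)
    utils::write.csv(x, p, row.names = FALSE, na = "", quote = FALSE)
    p
  }

  battery <- stage("battery", load_battery(cfg$battery))
  controls <- stage("read_controls", read_cohort(cfg$controls, battery))
  patients <- stage("read_patients", read_cohort(cfg$patients, battery))
  covariates <- if (!is.null(cfg$covariates))
    utils::read.csv(cfg$covariates, stringsAsFactors = FALSE) else NULL

  zs_pat <- stage("zscore", z_score_cohort(patients, covariates))
  zs_ctl <- stage("zscore", z_score_cohort(controls))

  tbl <- stage("summary_table", summarize_battery(zs_pat, battery))
  wcsv(tbl, "test_summary.csv")

  cutoffs <- cfg$impairment_cutoffs %||% c(-1.645, -1.5)
  base_rates <- stage("base_rates", {
    do.call(rbind, lapply(cutoffs, function(co) {
      do.call(rbind, lapply(SESSIONS, function(ss) {
        br <- impairment_base_rates(zs_pat, ss, co, k = 1:5)
        cbind(session = ss, cutoff = co, br$rates)
      }))
    }))
  })
  wcsv(base_rates, "impairment_base_rates.csv")

  chance <- stage("chance_simulation", {
    R <- estimate_null_correlation(zs_pat, "baseline")
    n_sub <- length(unique(zs_pat$subject_id[zs_pat$group == "patient"]))
    null <- simulate_chance_rates(
      n_tests = nrow(R), corr = R, cutoff = cutoffs[1],
      n_subjects = n_sub, n_reps = cfg$chance_n_reps %||% 10000,
      k = 1:2, seed = seed + 101L)
    obs <- base_rates[base_rates$session == "baseline" &
                        base_rates$cutoff == cutoffs[1], ]
    data.frame(k = 1:2,
               observed = obs$proportion[match(1:2, obs$k)],
               null_mean = null$mean_prop,
               p_value = vapply(1:2, function(kk)
                 chance_p_value(null, obs$proportion[obs$k == kk], kk),
                 numeric(1)))
  })
  wcsv(chance, "chance_test.csv")

  models <- stage("control_models", fit_control_models(zs_ctl, battery))
  wcsv(models, "control_models.csv")

  change <- stage("reliable_change", compute_change(
    zs_pat, models, battery, variant = cfg$rci_variant %||% "see",
    threshold = cfg$rci_threshold %||% 1.645))
  wcsv(change, "change_results.csv")

  dom <- stage("domain_change", domain_change(change, battery))
  wcsv(dom, "domain_change.csv")

  summ <- stage("change_summary", cohort_change_summary(
    change, battery, select_threshold = cfg$select_threshold %||% 0.20))
  wcsv(summ$by_test, "change_by_test.csv")
  wcsv(summ$by_domain, "change_by_domain.csv")
  wcsv(data.frame(test_id = summ$selected_tests), "selected_tests.csv")

  regression <- NULL
  if (!is.null(covariates)) {
    regression <- stage("outcome_models", {
      preds <- intersect(c("age_years", "kps", "tumor_ml", "codeleted_1p19q",
                           "high_grade", "hads_over_8", "chemoradiotherapy"),
                         names(covariates))
      outcomes <- c(stats::setNames(summ$selected_tests,
                                    summ$selected_tests))
      fits <- lapply(names(outcomes), function(tid) {
        sub <- change[change$test_id == tid, ]
        y <- sub$rci_class[match(covariates$subject_id, sub$subject_id)]
        keep <- !is.na(y)
        if (length(unique(y[keep] == "declined")) < 2) return(NULL)
        des <- covariates[keep, preds, drop = FALSE]
        tryCatch(
          rbind(fit_logistic(y[keep] == "declined", des, "univariable",
                             outcome_label = tid),
                fit_logistic(y[keep] == "declined", des, "multivariable",
                             outcome_label = tid)),
          error = function(e) {
            message("outcome '", tid, "' not modelled: ",
                    conditionMessage(e))
            NULL
          })
      })
      do.call(rbind, fits)
    })
    if (!is.null(regression)) wcsv(regression, "regression_models.csv")
    diag <- stage("diagnostics", {
      preds <- intersect(c("age_years", "kps", "tumor_ml", "codeleted_1p19q",
                           "high_grade", "hads_over_8", "chemoradiotherapy"),
                         names(covariates))
      # constant predictors (possible in small cohorts) carry no information
      # and would make the design rank-deficient
      informative <- vapply(preds, function(p)
        length(unique(stats::na.omit(covariates[[p]]))) > 1, logical(1))
      if (any(!informative))
        message("diagnostics: dropping constant predictor(s): ",
                paste(preds[!informative], collapse = ", "))
      preds <- preds[informative]
      d <- model_diagnostics(covariates[, preds, drop = FALSE])
      wcsv(d$vif, "diagnostics_vif.csv")
      if (!is.null(d$correlations)) wcsv(d$correlations,
                                         "diagnostics_correlations.csv")
      d
    })
  }

  maps <- NULL
  if (!is.null(cfg$masks) && dir.exists(cfg$masks %||% "")) {
    maps <- stage("lesion_overlay", {
      files <- list.files(cfg$masks, pattern = "\\.nii(\\.gz)?$",
                          full.names = TRUE)
      ids <- sub("\\.nii(\\.gz)?$", "", basename(files))
      ms <- read_masks(stats::setNames(files, ids),
                       stats::setNames(rep("all", length(ids)), ids))
      if (length(summ$selected_tests)) {
        tid <- summ$selected_tests[1]
        sub <- change[change$test_id == tid, ]
        classified <- sub$subject_id[!is.na(sub$rci_class)]
        usable <- intersect(names(ms$masks), classified)
        if (length(usable) < length(ms$masks))
          message("overlay: dropping ", length(ms$masks) - length(usable),
                  " mask(s) without a change classification for '", tid, "'")
        ms <- mask_set(ms$masks[usable], ms$group[usable],
                       affine = ms$affine)
        gm <- tryCatch(group_compare_maps(ms, change, tid),
                       error = function(e) {
                         message("overlay stage skipped: ",
                                 conditionMessage(e))
                         NULL
                       })
        if (!is.null(gm)) {
          write_overlay_nifti(gm$declined$overlay,
                              file.path(outdir, "overlay_declined.nii.gz"))
          write_overlay_nifti(gm$non_declined$overlay,
                              file.path(outdir,
                                        "overlay_non_declined.nii.gz"))
        }
        gm
      } else NULL
    })
  } else {
    message("no masks provided; overlay stage skipped")
  }

  cfg_path <- file.path(outdir, "config_used.yaml")
  yaml::write_yaml(cfg, cfg_path)
  manifest <- list(seed = seed,
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   package_version = as.character(
                     utils::packageVersion("cogchange")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   outputs = list.files(outdir))
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))

  invisible(list(summary_table = tbl, base_rates = base_rates,
                 chance = chance, control_models = models, change = change,
                 domain_change = dom, change_summary = summ,
                 regression = regression, maps = maps, outdir = outdir))
}
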