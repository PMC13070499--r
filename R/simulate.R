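#' Simulation configuration for synthetic two-session cohorts
#'
#' Bundles every parameter of the synthetic data generator: cohort sizes,
#' per-test retest reliability and practice effect, inter-test correlation,
#' patient baseline deficits per domain, a logistic decline model on the
#' seven clinical predictors, per-test decline magnitude, and per-test
#' missingness. The defaults emulate a glioma neuro-oncology study: 127
#' patients and 88 controls, retest reliability 0.7, a 0.3 z practice gain,
#' domain baseline deficits echoing the observed baseline z profile, decline
#' driven by age (OR 1.06/year) and chemoradiotherapy (OR 5), a 1.5 z
#' decline magnitude, and per-test missingness reproducing the observed
#' per-test n (85 to 126 of 127).
#'
#' @param n_controls,n_patients cohort sizes.
#' @param battery a `cog_battery`.
#' @param r12 per-test test-retest correlation in (0,1); scalar or named
#'   per-test vector.
#' @param practice_gain per-test mean retest gain in z units; scalar or
#'   per-test vector.
#' @param inter_test_corr common baseline correlation between tests in
#'   `[0,1)`, or a full correlation matrix.
#' @param patient_baseline_shift named per-domain mean z offset (<= 0 for
#'   deficits).
#' @param decline_model list with `intercept` and per-predictor log-odds
#'   coefficients (`age_years`, `kps`, `tumor_ml`, `codeleted_1p19q`,
#'   `high_grade`, `hads_over_8`, `chemoradiotherapy`), plus `magnitude`:
#'   per-test decline size in z units (scalar or per-test vector).
#' @param missing_rate per-test probability that a patient's score is
#'   missing; scalar or named per-test vector.
#' @param seed default RNG seed for the generators.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_controls = 88,
                       n_patients = 127,
                       battery = default_battery(),
                       r12 = 0.7,
                       practice_gain = 0.3,
                       inter_test_corr = 0.3,
                       patient_baseline_shift = c(
                         learning_memory = 0,
                         visuospatial_perceptual = -0.28,
                         language = -0.54,
                         executive = -0.46,
                         speed_attention = -0.31),
                       decline_model = list(
                         intercept = -5.1,
                         age_years = log(1.06),
                         kps = 0,
                         tumor_ml = 0,
                         codeleted_1p19q = 0,
                         high_grade = 0,
                         hads_over_8 = 0,
                         chemoradiotherapy = log(5),
                         magnitude = 1.5),
                       missing_rate = NULL,
                       seed = 1L) {
  nt <- nrow(battery)
  expand <- function(x, what) {
    if (length(x) == 1L) x <- stats::setNames(rep(x, nt), battery$test_id)
    if (is.null(names(x)) && length(x) == nt) names(x) <- battery$test_id
    miss <- setdiff(battery$test_id, names(x))
    if (length(miss)) stop(what, " missing for test(s): ",
                           paste(miss, collapse = ", "))
    x[battery$test_id]
  }
  r12 <- expand(r12, "r12")
  if (any(r12 <= 0 | r12 >= 1)) stop("r12 must lie in (0, 1)")
  practice_gain <- expand(practice_gain, "practice_gain")
  if (is.null(missing_rate)) {
    # per-test observed n out of 127 in the emulated study design
    obs_n <- c(bvmt_learning = 126, bvmt_recall = 126, ravlt_learning = 126,
               ravlt_recall = 125, tmt_a = 85, rey_cft_copy = 109, bnt = 105,
               phonemic_fluency = 110, semantic_fluency = 109, cwit1 = 105,
               cwit2 = 101, cwit3 = 105, cwit4 = 105, tmt_b = 85,
               digit_span_backward = 126, digit_span_forward = 126,
               coding = 86)
    missing_rate <- if (setequal(names(obs_n), battery$test_id))
      1 - obs_n / 127 else 0
  }
  missing_rate <- expand(missing_rate, "missing_rate")
  if (any(missing_rate < 0 | missing_rate > 1))
    stop("missing_rate must lie in [0, 1]")
  missd <- setdiff(unique(battery$domain), names(patient_baseline_shift))
  if (length(missd))
    stop("patient_baseline_shift missing for domain(s): ",
         paste(missd, collapse = ", "))
  decline_model$magnitude <- expand(decline_model$magnitude,
                                    "decline magnitude")
  corr <- as_corr_matrix(inter_test_corr, nt, "inter-test correlation")
  structure(list(n_controls = n_controls, n_patients = n_patients,
                 battery = battery, r12 = r12,
                 practice_gain = practice_gain, inter_test_corr = corr,
                 patient_baseline_shift = patient_baseline_shift,
                 decline_model = decline_model, missing_rate = missing_rate,
                 seed = seed),
            class = "sim_config")
}

# Map oriented z-scores to raw scores, inverting the orientation applied by
# z_transform (lower_better tests flip sign).
raw_from_z <- function(z, battery) {
  sgn <- ifelse(battery$polarity == "lower_better", -1, 1)
  sweep(sweep(z, 2, sgn * battery$norm_sd, "*"), 2, battery$norm_mean, "+")
}

# Draw paired (X1, Y2) z-score matrices for n subjects: baseline X ~ N(0, R),
# retest Y = gain + r12 * X + sqrt(1 - r12^2) * E with E ~ N(0, R), so each
# test has unit variances and baseline-retest correlation r12.
draw_paired_z <- function(n, cfg) {
  R <- cfg$inter_test_corr
  x <- rmvn(n, R)
  e <- rmvn(n, R)
  y <- sweep(sweep(x, 2, cfg$r12, "*") +
               sweep(e, 2, sqrt(1 - cfg$r12^2), "*"),
             2, cfg$practice_gain, "+")
  colnames(x) <- colnames(y) <- cfg$battery$test_id
  list(x = x, y = y)
}

paired_z_to_cohort <- function(x, y, ids, group, cfg) {
  battery <- cfg$battery
  raw1 <- raw_from_z(x, battery)
  raw2 <- raw_from_z(y, battery)
  wide <- function(raw, session) {
    df <- data.frame(subject_id = ids, group = group, session = session,
                     stringsAsFactors = FALSE)
    cbind(df, as.data.frame(raw))
  }
  df <- rbind(wide(raw1, "baseline"), wide(raw2, "followup"))
  new_cohort(df, battery)
}

#' Simulate a healthy control cohort with paired assessments
#'
#' Baseline z-scores are multivariate normal with the configured inter-test
#' correlation; retest scores have mean `baseline + practice_gain`, unit
#' variance, and baseline-retest correlation `r12` per test. Scores are
#' mapped to raw units through the battery norms and polarity. Controls are
#' complete (no missingness).
#'
#' @param cfg a [sim_config()].
#' @param seed RNG seed; defaults to `cfg$seed`.
#' @return A `cog_cohort` of raw scores.
#' @export
simulate_controls <- function(cfg, seed = cfg$seed) {
  local_seed(seed, {
    d <- draw_paired_z(cfg$n_controls, cfg)
    ids <- sprintf("ctrl%03d", seq_len(cfg$n_controls))
    paired_z_to_cohort(d$x, d$y, ids, "control", cfg)
  })
}

# Sample the seven clinical covariates with marginals echoing a typical
# lower-grade glioma cohort (median age ~41, KPS >= 80 in ~94%,
# chemoradiotherapy in ~79%).
simulate_covariates <- function(n, ids = sprintf("pat%03d", seq_len(n))) {
  age <- round(pmin(pmax(stats::rnorm(n, 42, 12), 19), 76))
  kps <- sample(c(60, 70, 80, 90, 100), n, replace = TRUE,
                prob = c(0.02, 0.04, 0.14, 0.40, 0.40))
  data.frame(subject_id = ids,
             age_years = age,
             kps = kps,
             tumor_ml = round(stats::rlnorm(n, log(30), 0.9), 1),
             codeleted_1p19q = stats::rbinom(n, 1, 0.41) == 1,
             high_grade = stats::rbinom(n, 1, 0.31) == 1,
             hads_over_8 = stats::rbinom(n, 1, 0.25) == 1,
             chemoradiotherapy = stats::rbinom(n, 1, 0.79) == 1,
             stringsAsFactors = FALSE)
}

#' Simulate a patient cohort with covariate-linked cognitive decline
#'
#' Patients share the control data-generating process plus a per-domain
#' baseline z offset. Each patient's decline indicator is drawn from a
#' logistic model on the seven clinical covariates; for declined patients the
#' retest mean is shifted down by the per-test decline magnitude before
#' noise. Per-test missingness is then applied to the scores. True decline
#' labels are returned so that recovery of sensitivity/specificity can be
#' tested against known truth.
#'
#' @param cfg a [sim_config()].
#' @param covariates optional pre-built covariate table (one row per
#'   patient, columns as [simulate_covariates()]); sampled if `NULL`.
#' @param seed RNG seed; defaults to `cfg$seed`.
#' @return list with `cohort` (a `cog_cohort`), `covariates` (data frame),
#'   and `truth` (long data frame `subject_id`, `test_id`, `true_decline`).
#' @export
simulate_patients <- function(cfg, covariates = NULL, seed = cfg$seed) {
  local_seed(seed, {
    n <- cfg$n_patients
    battery <- cfg$battery
    ids <- sprintf("pat%03d", seq_len(n))
    if (is.null(covariates)) covariates <- simulate_covariates(n, ids)
    cm <- cfg$decline_model
    eta <- cm$intercept +
      cm$age_years * covariates$age_years +
      cm$kps * covariates$kps +
      cm$tumor_ml * covariates$tumor_ml +
      cm$codeleted_1p19q * covariates$codeleted_1p19q +
      cm$high_grade * covariates$high_grade +
      cm$hads_over_8 * covariates$hads_over_8 +
      cm$chemoradiotherapy * covariates$chemoradiotherapy
    if (any(!is.finite(eta)))
      stop("decline model linear predictor is not finite for some subjects; ",
           "check coefficients and covariate scales")
    p_decline <- stats::plogis(eta)
    declined <- stats::rbinom(n, 1, p_decline) == 1

    d <- draw_paired_z(n, cfg)
    shift <- cfg$patient_baseline_shift[battery$domain]
    x <- sweep(d$x, 2, shift, "+")
    y <- sweep(d$y, 2, shift, "+")
    # true decline: declined subjects drop by the per-test magnitude
    drop <- outer(declined, cfg$decline_model$magnitude)
    y <- y - drop
    truth <- data.frame(
      subject_id = rep(ids, times = nrow(battery)),
      test_id = rep(battery$test_id, each = n),
      true_decline = as.vector(drop > 0),
      stringsAsFactors = FALSE)

    cohort <- paired_z_to_cohort(x, y, ids, "patient", cfg)
    # missingness: a test missing for a patient is missing at both sessions,
    # mirroring battery differences between sites rather than random dropout
    miss <- matrix(stats::runif(n * nrow(battery)), n) <
      matrix(cfg$missing_rate, n, nrow(battery), byrow = TRUE)
    for (j in seq_len(nrow(battery))) {
      tid <- battery$test_id[j]
      gone <- ids[miss[, j]]
      cohort[[tid]][cohort$subject_id %in% gone] <- NA_real_
    }
    list(cohort = cohort, covariates = covariates, truth = truth)
  })
}

#' Simulate co-registered binary tumour masks as jittered ellipsoids
#'
#' Generates, per group, `n_per_group` binary masks on a common voxel grid.
#' Each mask is an axis-aligned ellipsoid whose centre is jittered around
#' the group hotspot and whose radii are jittered around `radii`, emulating
#' registered tumour segmentations that cluster at a group-specific
#' location.
#'
#' @param n_per_group number of masks per group (recycled over groups).
#' @param grid_shape integer 3-vector of voxel dimensions.
#' @param hotspot_centers named list of 3-vectors (voxel coordinates), one
#'   per group.
#' @param spread SD (voxels) of the Gaussian jitter on mask centres.
#' @param radii base ellipsoid radii in voxels.
#' @param seed RNG seed.
#' @return A [mask_set()] whose subject ids are `<group><i>`.
#' @export
simulate_masks <- function(n_per_group, grid_shape = c(32, 32, 24),
                           hotspot_centers = list(
                             declined = c(10, 16, 12),
                             intact = c(22, 16, 12)),
                           spread = 2, radii = c(5, 4, 4), seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 1))
    stop("grid_shape must be a positive integer 3-vector")
  for (g in names(hotspot_centers)) {
    ctr <- hotspot_centers[[g]]
    if (length(ctr) != 3 || any(ctr < 1) || any(ctr > grid_shape))
      stop("hotspot center for group '", g, "' is outside the grid")
    if (any(ctr - 2 * spread - radii < 1) ||
        any(ctr + 2 * spread + radii > grid_shape))
      stop("grid too small for spread ", spread, " and radii around the '",
           g, "' hotspot; enlarge grid_shape or reduce spread")
  }
  local_seed(seed, {
    masks <- list()
    groups <- character(0)
    n_per_group <- rep_len(n_per_group, length(hotspot_centers))
    for (gi in seq_along(hotspot_centers)) {
      g <- names(hotspot_centers)[gi]
      for (i in seq_len(n_per_group[gi])) {
        ctr <- hotspot_centers[[g]] + round(stats::rnorm(3, 0, spread))
        # radii jitter scales with spread so spread = 0 gives identical masks
        jit <- min(0.04 * spread, 0.2)
        rad <- pmax(radii * stats::runif(3, 1 - jit, 1 + jit), 1)
        masks[[paste0(g, i)]] <- ellipsoid_mask(grid_shape, ctr, rad)
        groups <- c(groups, g)
      }
    }
    names(groups) <- names(masks)
    mask_set(masks, groups)
  })
}

ellipsoid_mask <- function(grid_shape, center, radii) {
  dx <- (seq_len(grid_shape[1]) - center[1]) / radii[1]
  dy <- (seq_len(grid_shape[2]) - center[2]) / radii[2]
  dz <- (seq_len(grid_shape[3]) - center[3]) / radii[3]
  d2 <- outer(outer(dx^2, dy^2, "+"), dz^2, "+")
  array(as.integer(d2 <= 1), dim = grid_shape)
}
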