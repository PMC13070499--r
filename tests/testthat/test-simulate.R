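test_that("simulated controls reproduce the configured moments", {
  b <- tiny_battery()
  cfg <- sim_config(n_controls = 10000, n_patients = 1, battery = b,
                    r12 = 0.7, practice_gain = 0.3, inter_test_corr = 0.3,
                    patient_baseline_shift = c(learning_memory = 0,
                                               language = 0, executive = 0),
                    missing_rate = 0, seed = 11)
  ctl <- simulate_controls(cfg)
  zs <- z_score_cohort(ctl)
  for (tid in b$test_id) {
    x1 <- zs$z[zs$test_id == tid & zs$session == "baseline"]
    y2 <- zs$z[zs$test_id == tid & zs$session == "followup"]
    expect_lt(abs(mean(y2 - x1) - 0.3), 0.02)    # practice effect
    expect_lt(abs(stats::cor(x1, y2) - 0.7), 0.02)  # retest reliability
    expect_lt(abs(stats::sd(x1) - 1), 0.03)
    expect_lt(abs(stats::sd(y2) - 1), 0.03)
  }
  # inter-test correlation at baseline
  base <- matrix(zs$z[zs$session == "baseline"], ncol = 3)
  offdiag <- stats::cor(base)[upper.tri(diag(3))]
  expect_true(all(abs(offdiag - 0.3) < 0.04))
})

test_that("near-perfect reliability makes retest track baseline", {
  cfg <- sim_config(n_controls = 200, battery = tiny_battery(), r12 = 0.999,
                    practice_gain = 0,
                    patient_baseline_shift = c(learning_memory = 0,
                                               language = 0, executive = 0),
                    missing_rate = 0, seed = 4)
  zs <- z_score_cohort(simulate_controls(cfg))
  x1 <- zs$z[zs$test_id == "memory" & zs$session == "baseline"]
  y2 <- zs$z[zs$test_id == "memory" & zs$session == "followup"]
  expect_gt(stats::cor(x1, y2), 0.99)
  expect_lt(max(abs(y2 - x1)), 0.5)
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- sim_config(n_controls = 30, n_patients = 20, seed = 7)
  expect_identical(simulate_controls(cfg), simulate_controls(cfg))
  expect_identical(simulate_patients(cfg), simulate_patients(cfg))
  ms1 <- simulate_masks(3, seed = 5)
  ms2 <- simulate_masks(3, seed = 5)
  expect_identical(ms1, ms2)
})

test_that("intercept-only decline model yields the intended prevalence", {
  cfg <- sim_config(
    n_patients = 2000, n_controls = 3, battery = tiny_battery(),
    patient_baseline_shift = c(learning_memory = 0, language = 0,
                               executive = 0),
    decline_model = list(intercept = cogchange:::logit(0.25), age_years = 0,
                         kps = 0, tumor_ml = 0, codeleted_1p19q = 0,
                         high_grade = 0, hads_over_8 = 0,
                         chemoradiotherapy = 0, magnitude = 1.5),
    missing_rate = 0, seed = 21)
  pats <- simulate_patients(cfg)
  prev <- mean(pats$truth$true_decline[pats$truth$test_id == "memory"])
  se <- sqrt(0.25 * 0.75 / 2000)
  expect_lt(abs(prev - 0.25), 2 * se)
})

test_that("a chemoradiotherapy log-odds of ln(5) is recovered in the truth labels", {
  cfg <- sim_config(
    n_patients = 5000, n_controls = 3, battery = tiny_battery(),
    patient_baseline_shift = c(learning_memory = 0, language = 0,
                               executive = 0),
    decline_model = list(intercept = cogchange:::logit(0.2), age_years = 0,
                         kps = 0, tumor_ml = 0, codeleted_1p19q = 0,
                         high_grade = 0, hads_over_8 = 0,
                         chemoradiotherapy = log(5), magnitude = 1.5),
    missing_rate = 0, seed = 22)
  pats <- simulate_patients(cfg)
  y <- pats$truth$true_decline[pats$truth$test_id == "memory"]
  y <- y[match(pats$covariates$subject_id,
               pats$truth$subject_id[pats$truth$test_id == "memory"])]
  x <- pats$covariates$chemoradiotherapy
  or <- (sum(y & x) * sum(!y & !x)) / (sum(!y & x) * sum(y & !x))
  expect_lt(abs(or - 5) / 5, 0.25)
})

test_that("null patients are indistinguishable from controls", {
  b <- tiny_battery()
  cfg <- sim_config(
    n_controls = 500, n_patients = 500, battery = b,
    patient_baseline_shift = c(learning_memory = 0, language = 0,
                               executive = 0),
    decline_model = list(intercept = -30, age_years = 0, kps = 0,
                         tumor_ml = 0, codeleted_1p19q = 0, high_grade = 0,
                         hads_over_8 = 0, chemoradiotherapy = 0,
                         magnitude = 0),
    missing_rate = 0, seed = 23)
  ctl <- simulate_controls(cfg)
  pats <- simulate_patients(cfg)
  zs_c <- z_score_cohort(ctl)
  zs_p <- z_score_cohort(pats$cohort)
  dz <- function(zs, tid) {
    x1 <- zs$z[zs$test_id == tid & zs$session == "baseline"]
    y2 <- zs$z[zs$test_id == tid & zs$session == "followup"]
    y2 - x1
  }
  for (tid in b$test_id)
    expect_gt(stats::t.test(dz(zs_c, tid), dz(zs_p, tid))$p.value, 0.01)
})

test_that("patient missingness matches the configured per-test rates", {
  cfg <- sim_config(n_patients = 2000, n_controls = 3,
                    battery = tiny_battery(),
                    patient_baseline_shift = c(learning_memory = 0,
                                               language = 0, executive = 0),
                    missing_rate = c(memory = 0, naming = 0.3, trails = 0.1),
                    seed = 24)
  pats <- simulate_patients(cfg)
  base <- pats$cohort[pats$cohort$session == "baseline", ]
  expect_equal(mean(is.na(base$memory)), 0)
  expect_lt(abs(mean(is.na(base$naming)) - 0.3), 0.03)
  expect_lt(abs(mean(is.na(base$trails)) - 0.1), 0.02)
})

test_that("synthetic masks respect geometry and determinism", {
  # zero spread: identical masks, overlay max equals group size
  ms <- simulate_masks(4, spread = 0, seed = 9)
  g <- names(ms$group)[ms$group == ms$group[1]]
  expect_true(all(vapply(ms$masks[g[-1]],
                         function(m) identical(m, ms$masks[[g[1]]]),
                         logical(1))))
  ov <- build_overlay(ms, ms$group[[1]])
  expect_equal(ov$group_max, 4)

  # opposite hotspots land in opposite x-halves
  ms2 <- simulate_masks(6, grid_shape = c(40, 32, 24),
                        hotspot_centers = list(left = c(12, 16, 12),
                                               right = c(28, 16, 12)),
                        spread = 1, seed = 10)
  centroid_x <- function(counts) {
    w <- apply(counts, 1, sum)
    sum(seq_along(w) * w) / sum(w)
  }
  cl <- centroid_x(build_overlay(ms2, "left")$counts)
  cr <- centroid_x(build_overlay(ms2, "right")$counts)
  expect_lt(cl, 20.5)
  expect_gt(cr, 20.5)

  expect_error(simulate_masks(2, grid_shape = c(10, 10, 10), spread = 5,
                              hotspot_centers = list(g = c(5, 5, 5))),
               "too small")
})
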