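test_that("control regression recovers exact linear relationships", {
  x1 <- c(-1, -0.5, 0, 0.5, 1, 1.5)
  # perfect line: y2 = 0.5 + 0.9 x1
  zs <- zs_from_pairs(x1, 0.5 + 0.9 * x1)
  m <- fit_control_regression(zs, "memory")
  expect_equal(m$b0, 0.5, tolerance = 1e-10)
  expect_equal(m$b1, 0.9, tolerance = 1e-10)
  expect_equal(m$see, 0, tolerance = 1e-10)
  expect_equal(m$x_bar, mean(x1))
  expect_equal(m$ss_x, sum((x1 - mean(x1))^2))

  # identity retest
  m2 <- fit_control_regression(zs_from_pairs(x1, x1), "memory")
  expect_equal(m2$b0, 0, tolerance = 1e-10)
  expect_equal(m2$b1, 1, tolerance = 1e-10)
})

test_that("control regression errors on degenerate input", {
  expect_error(fit_control_regression(zs_from_pairs(c(1, 1, 1, 1),
                                                    c(0, 1, 2, 3)),
                                      "memory"),
               "all control baselines are equal")
  expect_error(fit_control_regression(zs_from_pairs(c(0, 1), c(0, 1)),
                                      "memory"),
               "insufficient")
})

test_that("fitted slope and intercept match bivariate-normal theory", {
  # X ~ N(0,1), Y = 0.3 + 0.7 X + sqrt(1-0.49) E: slope 0.7, intercept 0.3
  cfg <- sim_config(n_controls = 10000, battery = tiny_battery(), r12 = 0.7,
                    practice_gain = 0.3,
                    patient_baseline_shift = c(learning_memory = 0,
                                               language = 0, executive = 0),
                    missing_rate = 0, seed = 41)
  zs <- z_score_cohort(simulate_controls(cfg))
  m <- fit_control_regression(zs, "memory")
  expect_lt(abs(m$b1 - 0.7), 0.03)
  expect_lt(abs(m$b0 - 0.3), 0.03)
  expect_lt(abs(m$see - sqrt(1 - 0.49)), 0.03)
})

test_that("rci matches hand arithmetic and the prediction variant converges to see", {
  m <- data.frame(test_id = "memory", n_controls = 1e6, b0 = 0.5, b1 = 0.9,
                  see = 0.6, x_bar = 0, ss_x = 1e6, r12 = 0.9)
  expect_equal(rci(0, -1.0, m, "see"), -2.5)
  expect_equal(as.character(classify_change(rci(0, -1.0, m, "see"))),
               "declined")
  # y2 at prediction -> rci 0, stable
  expect_equal(rci(1, 0.5 + 0.9, m, "see"), 0)
  # prediction variant equals see variant at x1 = x_bar for huge n
  expect_equal(rci(0, -1.0, m, "prediction"), rci(0, -1.0, m, "see"),
               tolerance = 1e-3)
  # prediction variant widens the denominator away from the control mean
  m$n_controls <- 20; m$ss_x <- 10
  expect_lt(abs(rci(3, -1, m, "prediction")), abs(rci(3, -1, m, "see")))

  m$see <- 0
  expect_error(rci(0, 1, m), "degenerate")
  m$see <- 0.6
  expect_true(is.na(rci(NA, 1, m)))
  expect_true(is.na(rci(1, NA, m)))
})

test_that("change classification uses strict thresholds on both criteria", {
  expect_equal(as.character(classify_change(c(-2.5, 0, 2.0, -1.645, 1.645))),
               c("declined", "stable", "improved", "stable", "stable"))
  dz <- delta_z_classify(c(0.2, 0, 0), c(-0.9, 0, -1.0))
  expect_equal(dz$delta_z, c(-1.1, 0, -1.0))
  # delta-z decline boundary is inclusive, unlike the RCI threshold
  expect_equal(as.character(dz$deltaz_class), c("declined", "stable",
                                                "declined"))
})

test_that("null calibration: ~5% flagged per tail on fresh null subjects", {
  b <- tiny_battery()
  cfg <- sim_config(n_controls = 5000, battery = b, r12 = 0.7,
                    practice_gain = 0.3,
                    patient_baseline_shift = c(learning_memory = 0,
                                               language = 0, executive = 0),
                    missing_rate = 0, seed = 42)
  models <- fit_control_models(z_score_cohort(simulate_controls(cfg)), b)
  fresh <- z_score_cohort(simulate_controls(cfg, seed = 43))
  ch <- compute_change(fresh, models, b, group = "control")
  dec <- mean(ch$rci_class == "declined", na.rm = TRUE)
  imp <- mean(ch$rci_class == "improved", na.rm = TRUE)
  se <- sqrt(0.05 * 0.95 / 5000)
  expect_lt(abs(dec - 0.05), 3 * se)
  expect_lt(abs(imp - 0.05), 3 * se)
})

test_that("RCI flags a non-learner that delta-z misses under practice effects", {
  # controls gain 0.3 z on retest; a patient with unchanged scores at the
  # control baseline mean fails to show that gain
  m <- data.frame(test_id = "memory", n_controls = 100, b0 = 0.3, b1 = 0.9,
                  see = 0.5, x_bar = 0, ss_x = 99, r12 = 0.9)
  x1 <- 0; y2 <- 0
  expect_lt(rci(x1, y2, m), 0)
  expect_equal(rci(x1, y2, m), -0.3 / 0.5)
  dz <- delta_z_classify(x1, y2)
  expect_equal(dz$delta_z, 0)
  expect_equal(as.character(dz$deltaz_class), "stable")
})

test_that("regression to the mean differentiates equal raw changes", {
  # slope < 1: same observed change, baselines symmetric about x_bar
  m <- data.frame(test_id = "memory", n_controls = 100, b0 = 0, b1 = 0.7,
                  see = 0.5, x_bar = 0, ss_x = 99, r12 = 0.7)
  lo <- rci(-1, -1.5, m)   # low baseline, drop of 0.5
  hi <- rci(1, 0.5, m)     # high baseline, same drop
  expect_false(isTRUE(all.equal(lo, hi)))
  # closed-form oracle recomputation
  expect_equal(lo, (-1.5 - (0 + 0.7 * -1)) / 0.5)
  expect_equal(hi, (0.5 - (0 + 0.7 * 1)) / 0.5)
  expect_lt(lo, hi)  # the low-baseline subject is penalised more
})

test_that("declines simulated with known truth are recovered above chance", {
  b <- tiny_battery()
  shifts <- c(1.0, 1.5, 2.5)
  sens <- vapply(seq_along(shifts), function(i) {
    cfg <- sim_config(
      n_controls = 1000, n_patients = 1000, battery = b, r12 = 0.7,
      practice_gain = 0.3,
      patient_baseline_shift = c(learning_memory = 0, language = 0,
                                 executive = 0),
      decline_model = list(intercept = cogchange:::logit(0.3),
                           age_years = 0, kps = 0, tumor_ml = 0,
                           codeleted_1p19q = 0, high_grade = 0,
                           hads_over_8 = 0, chemoradiotherapy = 0,
                           magnitude = shifts[i]),
      missing_rate = 0, seed = 44)
    models <- fit_control_models(z_score_cohort(simulate_controls(cfg)), b)
    pats <- simulate_patients(cfg, seed = 45)
    ch <- compute_change(z_score_cohort(pats$cohort), models, b)
    truth <- pats$truth$true_decline[match(
      paste(ch$subject_id, ch$test_id),
      paste(pats$truth$subject_id, pats$truth$test_id))]
    spec <- mean(ch$rci_class[!truth] != "declined", na.rm = TRUE)
    expect_gt(spec, 0.9)  # specificity stays high at every shift
    mean(ch$rci_class[truth] == "declined", na.rm = TRUE)
  }, numeric(1))
  expect_gt(sens[1], 0.3)            # above the 5% chance rate
  expect_true(all(diff(sens) > 0))   # monotone in the decline magnitude
})

test_that("domain averages follow the per-test RCIs", {
  b <- tiny_battery()
  ch <- data.frame(
    subject_id = rep("p1", 3),
    test_id = c("memory", "naming", "trails"),
    x1 = 0, y2 = 0, y2_hat = 0,
    rci = c(-2.0, -1.4, NA),
    rci_class = classify_change(c(-2.0, -1.4, NA)),
    delta_z = 0,
    deltaz_class = factor("stable", levels = c("declined", "stable")))
  attr(ch, "battery") <- b
  class(ch) <- c("change_results", "data.frame")
  dom <- domain_change(ch, b)
  # single-test domains: the average is the test's RCI
  expect_equal(dom$mean_rci[dom$domain == "learning_memory"], -2.0)
  expect_equal(as.character(dom$class[dom$domain == "learning_memory"]),
               "declined")
  expect_equal(dom$mean_rci[dom$domain == "language"], -1.4)
  expect_equal(as.character(dom$class[dom$domain == "language"]), "stable")
  # all RCIs missing in a domain -> missing domain result
  expect_true(is.na(dom$mean_rci[dom$domain == "executive"]))
  expect_true(is.na(dom$class[dom$domain == "executive"]))

  # a two-test domain averages to the mean RCI
  b2 <- cogchange:::new_battery(data.frame(
    test_id = c("m1", "m2"), display_name = c("m1", "m2"),
    domain = "learning_memory", subdomain = "verbal",
    polarity = "higher_better", rci_eligible = TRUE,
    norm_mean = 50, norm_sd = 10))
  ch2 <- data.frame(subject_id = "p1", test_id = c("m1", "m2"),
                    x1 = 0, y2 = 0, y2_hat = 0, rci = c(-2.0, -1.4),
                    rci_class = classify_change(c(-2.0, -1.4)),
                    delta_z = 0,
                    deltaz_class = factor("stable",
                                          levels = c("declined", "stable")))
  attr(ch2, "battery") <- b2
  class(ch2) <- c("change_results", "data.frame")
  dom2 <- domain_change(ch2, b2)
  expect_equal(dom2$mean_rci, -1.7)
  expect_equal(as.character(dom2$class), "declined")
})

test_that("RCI-ineligible tests never contribute an RCI", {
  b <- default_battery()
  cfg <- sim_config(n_controls = 50, n_patients = 20, seed = 46)
  ctl <- simulate_controls(cfg)
  pats <- simulate_patients(cfg)
  models <- fit_control_models(z_score_cohort(ctl), b)
  expect_false("rey_cft_copy" %in% models$test_id)
  ch <- compute_change(z_score_cohort(pats$cohort), models, b)
  rey <- ch[ch$test_id == "rey_cft_copy", ]
  expect_true(all(is.na(rey$rci)))
  expect_true(any(!is.na(rey$delta_z)))  # delta-z still available
})

test_that("cohort change summary enumerates proportions and applies the strict >20% rule", {
  b <- tiny_battery()
  cls <- classify_change(c(-2, 0, 0, 2))
  ch <- data.frame(subject_id = sprintf("p%d", 1:4), test_id = "memory",
                   x1 = 0, y2 = 0, y2_hat = 0, rci = c(-2, 0, 0, 2),
                   rci_class = cls, delta_z = 0,
                   deltaz_class = factor("stable",
                                         levels = c("declined", "stable")))
  attr(ch, "battery") <- b
  class(ch) <- c("change_results", "data.frame")
  s <- cohort_change_summary(ch, b)
  row <- s$by_test[s$by_test$test_id == "memory", ]
  expect_equal(row$prop_declined, 0.25)
  expect_equal(row$prop_improved, 0.25)
  expect_true("memory" %in% s$selected_tests)

  # exactly 20% declined is NOT selected (strict inequality)
  cls5 <- classify_change(c(-2, 0, 0, 0, 0))
  ch5 <- data.frame(subject_id = sprintf("p%d", 1:5), test_id = "memory",
                    x1 = 0, y2 = 0, y2_hat = 0, rci = c(-2, 0, 0, 0, 0),
                    rci_class = cls5, delta_z = 0,
                    deltaz_class = factor("stable",
                                          levels = c("declined", "stable")))
  attr(ch5, "battery") <- b
  class(ch5) <- c("change_results", "data.frame")
  s5 <- cohort_change_summary(ch5, b)
  expect_equal(s5$by_test$prop_declined[s5$by_test$test_id == "memory"], 0.2)
  expect_false("memory" %in% s5$selected_tests)

  # all stable -> zero proportions everywhere
  ch$rci_class <- classify_change(rep(0, 4))
  ch$rci <- 0
  s0 <- cohort_change_summary(ch, b)
  expect_equal(s0$by_test$prop_declined[s0$by_test$test_id == "memory"], 0)
  expect_length(s0$selected_tests, 0)
})

test_that("control models round-trip through CSV", {
  x1 <- c(-1.2, -0.4, 0.1, 0.6, 1.3, 0.2)
  zs <- zs_from_pairs(x1, 0.3 + 0.8 * x1 + c(0.1, -0.2, 0.05, 0.1, -0.1, 0))
  m <- fit_control_models(zs, tiny_battery()[1, ])
  path <- withr::local_tempfile(fileext = ".csv")
  write_control_models(m, path)
  m2 <- read_control_models(path)
  expect_equal(m2$b0, m$b0, tolerance = 1e-12)
  expect_equal(m2$see, m$see, tolerance = 1e-12)
})
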