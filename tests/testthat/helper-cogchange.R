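# Small fixtures shared across tests; everything is built in code.

# A three-test battery spanning three domains, with one timed test and one
# RCI-ineligible test.
tiny_battery <- function() {
  cogchange:::new_battery(data.frame(
    test_id = c("memory", "naming", "trails"),
    display_name = c("Word list", "Naming", "Trails"),
    domain = c("learning_memory", "language", "executive"),
    subdomain = c("verbal", "visuoperceptual", "speed"),
    polarity = c("higher_better", "higher_better", "lower_better"),
    rci_eligible = c(TRUE, TRUE, TRUE),
    norm_mean = c(50, 54, 60),
    norm_sd = c(10, 3, 10),
    stringsAsFactors = FALSE))
}

# Wide cohort data frame for a handful of subjects and both sessions.
tiny_cohort <- function(battery = tiny_battery()) {
  df <- data.frame(
    subject_id = rep(c("p1", "p2", "c1", "c2", "c3", "c4"), each = 2),
    group = rep(c("patient", "patient", "control", "control", "control",
                  "control"), each = 2),
    session = rep(c("baseline", "followup"), 6),
    memory = c(45, 40, 55, 56, 50, 53, 60, 61, 40, 44, 52, 55),
    naming = c(50, 49, 54, 55, 51, 52, 56, 57, 49, 51, 53, 54),
    trails = c(80, 85, 55, 50, 62, 60, 45, 44, 75, 70, 58, 57),
    stringsAsFactors = FALSE)
  new_cohort(df, battery)
}

# Build a zscore_table directly from per-test (x1, y2) z-score vectors.
zs_from_pairs <- function(x1, y2, test_id = "memory", group = "control",
                          battery = tiny_battery()) {
  n <- length(x1)
  ids <- sprintf("%s%04d", substr(group, 1, 1), seq_len(n))
  out <- data.frame(
    subject_id = rep(ids, 2),
    group = group,
    session = rep(c("baseline", "followup"), each = n),
    test_id = test_id,
    z = c(x1, y2),
    stringsAsFactors = FALSE)
  attr(out, "battery") <- battery
  class(out) <- c("zscore_table", "data.frame")
  out
}

# Independent brute-force two-sided Fisher p by hypergeometric enumeration
# over all tables with the observed margins (point-probability method, with
# the same relative tolerance R uses when comparing point probabilities).
fisher_bruteforce <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  a_vals <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(a_vals, function(a)
    exp(lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(n, c1)), numeric(1))
  p_obs <- probs[a_vals == m[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
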