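# Shared fixtures and independent oracles, built in code at test time.

# Brute-force Mann-Whitney AUC: enumerate every event x non-event pair,
# ties credited 1/2. Deliberately naive and independent of the package's
# placement-value implementation.
brute_auc <- function(pred, events) {
  x <- pred[events == 1]
  y <- pred[events == 0]
  cmp <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Random small dataset with ties (discrete scores) for oracle comparisons.
random_scored_data <- function(n = 30) {
  events <- c(1, 0, rbinom(n - 2, 1, 0.4))  # guarantee both classes
  pred <- sample(seq(0.05, 0.95, by = 0.05), n, replace = TRUE)
  list(pred = pred, events = events)
}

# Minimal hand-checkable cohort in the canonical schema.
toy_cohort <- function() {
  data.frame(
    subject_id = paste0("T", 1:5),
    sex = c("female", "female", "male", "male", "female"),
    age = c(65, 72, 68, 80, 75),
    fn_bmd = c(0.85, 0.70, 0.95, 0.80, NA),
    tscore = c(NA, NA, NA, NA, -2.1),
    weight = c(70, 62, 85, 78, 66),
    prior_fractures = c(0, 1, 0, 2, 3),
    falls_12mo = c(0, 1, 0, 2, 1),
    time_any = c(8.0, 3.2, 8.0, 1.5, 6.0),
    event_any = c(0, 1, 0, 1, 1),
    time_hip = c(8.0, 8.0, 8.0, 1.5, 6.0),
    event_hip = c(0, 0, 0, 1, 0),
    died = c(0, 0, 0, 0, 0),
    stringsAsFactors = FALSE
  )
}

# Random valid cohort of predictor rows (no outcomes) for engine tests.
random_profiles <- function(n, seed) {
  withr::with_seed(seed, {
    sex <- sample(c("female", "male"), n, replace = TRUE)
    data.frame(
      subject_id = as.character(seq_len(n)),
      sex = sex,
      age = runif(n, 60, 95),
      fn_bmd = runif(n, 0.5, 1.2),
      tscore = NA_real_,
      weight = runif(n, 45, 110),
      prior_fractures = sample(0:3, n, replace = TRUE),
      falls_12mo = sample(0:2, n, replace = TRUE),
      stringsAsFactors = FALSE
    )
  })
}

# Reference panel: eight profiles spanning both sexes, both outcomes and
# both model variants. Expected values were frozen from an independent
# hand evaluation of the shipped equation document (coefficients typed
# directly into risk = 1 - s0^exp(lp - lp_center), bypassing the package's
# parser and engine).
reference_panel <- function() {
  list(
    list(p = risk_profile("female", 70, tscore = -2.0, prior_fractures = 1,
                          falls_12mo = 1),
         outcome = "hip", horizon = 10, variant = "bmd",
         expected = 0.1089596547),
    list(p = risk_profile("female", 65, fn_bmd = 0.90),
         outcome = "any", horizon = 5, variant = "bmd",
         expected = 0.0426001235),
    list(p = risk_profile("female", 80, tscore = -2.5, prior_fractures = 2,
                          falls_12mo = 2),
         outcome = "hip", horizon = 5, variant = "bmd",
         expected = 0.4134395237),
    list(p = risk_profile("male", 70, tscore = -1.0),
         outcome = "any", horizon = 10, variant = "bmd",
         expected = 0.0854444980),
    list(p = risk_profile("male", 75, tscore = -2.0, prior_fractures = 1),
         outcome = "hip", horizon = 10, variant = "bmd",
         expected = 0.0957921274),
    list(p = risk_profile("female", 70, weight = 60, prior_fractures = 1,
                          falls_12mo = 1),
         outcome = "any", horizon = 10, variant = "weight",
         expected = 0.4258903168),
    list(p = risk_profile("male", 72, weight = 85, falls_12mo = 1),
         outcome = "hip", horizon = 5, variant = "weight",
         expected = 0.0090142574),
    list(p = risk_profile("male", 68, weight = 95, prior_fractures = 3,
                          falls_12mo = 2),
         outcome = "any", horizon = 5, variant = "weight",
         expected = 0.2357354189)
  )
}
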