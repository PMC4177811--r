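test_that("cohort tables round-trip through delimited text", {
  df <- toy_cohort()
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_cohort(df, tmp)
  back <- read_cohort(tmp)
  expect_equal(nrow(back), 5L)
  expect_identical(back$subject_id, df$subject_id)
  expect_equal(back$age, df$age)
  expect_equal(back$fn_bmd, df$fn_bmd)
  expect_equal(back$event_any, df$event_any)
  # configurable separator
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(df, tmp2, sep = "\t")
  expect_equal(read_cohort(tmp2, sep = "\t")$time_any, df$time_any)
})

test_that("schema mapping renames columns and flags missing ones", {
  df <- toy_cohort()
  names(df)[names(df) == "falls_12mo"] <- "falls"
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_cohort(df, tmp)
  back <- read_cohort(tmp, schema = cohort_schema(falls_12mo = "falls"))
  expect_equal(back$falls_12mo, toy_cohort()$falls_12mo)
  # default schema maps falls_12mo, which this file lacks
  expect_error(read_cohort(tmp), "falls_12mo")
  expect_error(cohort_schema(not_a_field = "x"), "unknown schema field")
})

test_that("row-level validation names the offending subject", {
  tmp <- withr::local_tempfile(fileext = ".csv")

  df <- toy_cohort(); df$time_any[3] <- -1
  write_cohort(df, tmp)
  expect_error(read_cohort(tmp), "subject T3.*time_any must be > 0")

  df <- toy_cohort(); df$age[2] <- "seventy"
  write_cohort(df, tmp)
  expect_error(read_cohort(tmp), "subject T2: unparseable value 'seventy'")

  df <- toy_cohort(); df$event_hip[1] <- 2
  write_cohort(df, tmp)
  expect_error(read_cohort(tmp), "subject T1.*0 or 1")

  df <- toy_cohort(); df$event_hip[1] <- 1; df$event_any[1] <- 0
  write_cohort(df, tmp)
  expect_error(read_cohort(tmp), "subset")

  expect_error(read_cohort(file.path(tempdir(), "no-such-file.csv")),
               "not found")
})

test_that("missing predictor cells pass read-time and are counted per variant", {
  df <- toy_cohort()
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_cohort(df, tmp)
  back <- read_cohort(tmp)
  expect_identical(predictor_completeness(back), c(bmd = 0L, weight = 0L))
  df$weight[2] <- NA
  df$fn_bmd[1] <- NA   # T1 has no tscore either
  write_cohort(df, tmp)
  back <- read_cohort(tmp)
  expect_identical(predictor_completeness(back), c(bmd = 1L, weight = 1L))
  expect_error(predict_cohort(back, "any", 10, "bmd"), "invalid record T1")
})

test_that("follow-up summaries match hand tallies and printed-cohort arithmetic", {
  df <- toy_cohort()
  s <- summarize_followup(df, "any")
  expect_equal(s$n_subjects, 5)
  expect_equal(s$n_events, 3)
  expect_equal(s$person_years, 8.0 + 3.2 + 8.0 + 1.5 + 6.0)
  s_hip <- summarize_followup(df, "hip")
  expect_equal(s_hip$n_events, 1)
  expect_equal(s_hip$person_years, 8.0 + 8.0 + 8.0 + 1.5 + 6.0)

  one <- df[1, , drop = FALSE]; one$time_any <- 2.5; one$event_any <- 0
  s1 <- summarize_followup(one, "any")
  expect_equal(unlist(s1[c("n_subjects", "n_events", "person_years")]),
               c(n_subjects = 1, n_events = 0, person_years = 2.5))

  # a cohort of 1637 subjects with mean follow-up 6.9 years
  big <- data.frame(time_any = rep(6.9, 1637), event_any = 0)
  sb <- summarize_followup(big, "any")
  expect_equal(sb$person_years, 11295.3)

  expect_error(summarize_followup(df[0, ], "any"), "empty cohort")
})

test_that("incidence rates and exact Poisson intervals are correct", {
  r1 <- incidence_rate(list(n_events = 356, person_years = 11295.3))
  expect_equal(round(r1$rate, 1), 31.5)
  r2 <- incidence_rate(list(n_events = 117, person_years = 9620.5))
  expect_equal(round(r2$rate, 1), 12.2)
  # zero events: rate 0, exact upper bound from the gamma quantile
  r0 <- incidence_rate(list(n_events = 0, person_years = 100))
  expect_equal(r0$rate, 0)
  expect_equal(r0$ci_low, 0)
  expect_equal(r0$ci_high, 1000 * qgamma(0.975, 1) / 100, tolerance = 1e-12)
  expect_equal(r0$ci_high, 36.89, tolerance = 1e-3)
  expect_error(incidence_rate(list(n_events = 3, person_years = 0)),
               "person_years")
  expect_error(incidence_rate(list(n_events = 0, person_years = 10),
                              ci_method = "lognormal"), "zero events")
})

test_that("summaries are additive over strata and rates behave under rescaling", {
  co <- garvan_coefficients()
  cohort <- generate_cohort(cohort_config(n = 800), co, seed = 11)
  split_at <- 400
  a <- cohort[1:split_at, ]; b <- cohort[(split_at + 1):800, ]
  for (outcome in c("any", "hip")) {
    whole <- summarize_followup(cohort, outcome)
    sa <- summarize_followup(a, outcome); sb <- summarize_followup(b, outcome)
    expect_equal(sa$n_events + sb$n_events, whole$n_events)
    expect_equal(sa$person_years + sb$person_years, whole$person_years)
  }
  # order invariance
  shuf <- cohort[sample(nrow(cohort)), ]
  expect_equal(incidence_rate(summarize_followup(shuf, "any"))$rate,
               incidence_rate(summarize_followup(cohort, "any"))$rate)
  # scaling all follow-up times by c scales the rate by 1/c
  scaled <- cohort; scaled$time_any <- scaled$time_any * 2
  expect_equal(incidence_rate(summarize_followup(scaled, "any"))$rate,
               incidence_rate(summarize_followup(cohort, "any"))$rate / 2)
})

test_that("the exact interval contains the rate and narrows with person-years", {
  widths <- vapply(c(1, 4, 16), function(k) {
    r <- incidence_rate(list(n_events = 20 * k, person_years = 1000 * k))
    expect_gte(r$rate, r$ci_low)
    expect_lte(r$rate, r$ci_high)
    r$ci_high - r$ci_low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})
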