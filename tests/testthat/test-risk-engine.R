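
test_that("engine reproduces the frozen hand-evaluated reference panel", {
  co <- garvan_coefficients()
  for (case in reference_panel()) {
    est <- predict_risk(case$p, case$outcome, case$horizon, case$variant, co)
    expect_equal(est$probability, case$expected, tolerance = 1e-8,
                 label = paste(case$p$sex, case$outcome, case$horizon,
                               case$variant))
  }
})

test_that("predictions stay strictly inside (0, 1) over a dense domain grid", {
  co <- garvan_coefficients()
  grid <- expand.grid(sex = c("female", "male"), age = c(50, 60, 75, 95, 110),
                      tscore = c(-4.5, -2.5, 0, 2.5),
                      weight = c(30, 60, 100, 240),
                      fx = c(0, 3), falls = c(0, 2),
                      outcome = c("hip", "any"), horizon = c(5, 10),
                      variant = c("bmd", "weight"),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    p <- risk_profile(g$sex, g$age, tscore = g$tscore, weight = g$weight,
                      prior_fractures = g$fx, falls_12mo = g$falls)
    prob <- predict_risk(p, g$outcome, g$horizon, g$variant, co)$probability
    expect_true(prob > 0 && prob < 1)
  }
})

test_that("risk is monotone in each risk factor and in the horizon", {
  co <- garvan_coefficients()
  base <- expand.grid(sex = c("female", "male"), outcome = c("hip", "any"),
                      variant = c("bmd", "weight"), horizon = c(5, 10),
                      stringsAsFactors = FALSE)
  risk_of <- function(sex, outcome, variant, horizon, age = 70, tscore = -1.5,
                      weight = 70, fx = 0, falls = 0) {
    p <- risk_profile(sex, age, tscore = tscore, weight = weight,
                      prior_fractures = fx, falls_12mo = falls)
    predict_risk(p, outcome, horizon, variant, co)$probability
  }
  for (i in seq_len(nrow(base))) {
    b <- base[i, ]
    args <- list(b$sex, b$outcome, b$variant, b$horizon)
    # age, strictly increasing over [60, 95]
    by_age <- vapply(seq(60, 95, by = 5),
                     function(a) do.call(risk_of, c(args, age = a)), numeric(1))
    expect_true(all(diff(by_age) > 0))
    # falls and prior-fracture categories, non-decreasing
    by_falls <- vapply(0:4, function(k) do.call(risk_of, c(args, falls = k)),
                       numeric(1))
    expect_true(all(diff(by_falls) >= 0))
    by_fx <- vapply(0:5, function(k) do.call(risk_of, c(args, fx = k)),
                    numeric(1))
    expect_true(all(diff(by_fx) >= 0))
    if (b$variant == "bmd") {
      by_t <- vapply(seq(-3, 1, by = 0.5),
                     function(t) do.call(risk_of, c(args, tscore = t)),
                     numeric(1))
      expect_true(all(diff(by_t) < 0))  # higher BMD, lower risk
    } else {
      block <- co$blocks[[paste(ifelse(b$outcome == "hip", "hip", "any"),
                                b$sex, "weight", sep = "_")]]
      by_w <- vapply(seq(45, 110, by = 5),
                     function(w) do.call(risk_of, c(args, weight = w)),
                     numeric(1))
      expect_true(all(sign(diff(by_w)) == sign(block$weight)))
    }
    # 10-year risk never below 5-year risk
    expect_gte(do.call(risk_of, c(args[-4], horizon = 10)),
               do.call(risk_of, c(args[-4], horizon = 5)))
  }
})

test_that("supplying BMD or the equivalent T-score gives identical predictions", {
  co <- garvan_coefficients()
  for (sex in c("female", "male")) {
    for (bmd in c(0.65, 0.83, 1.10)) {
      t <- bmd_to_tscore(bmd, sex, co)
      p_bmd <- risk_profile(sex, 73, fn_bmd = bmd, prior_fractures = 1)
      p_t <- risk_profile(sex, 73, tscore = t, prior_fractures = 1)
      for (outcome in c("hip", "any")) {
        expect_equal(predict_risk(p_bmd, outcome, 10, "bmd", co)$probability,
                     predict_risk(p_t, outcome, 10, "bmd", co)$probability,
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("counts above the top category are clamped to it", {
  co <- garvan_coefficients()
  r <- function(fx, falls) {
    p <- risk_profile("female", 75, tscore = -2, prior_fractures = fx,
                      falls_12mo = falls)
    predict_risk(p, "any", 10, "bmd", co)$probability
  }
  expect_equal(r(7, 0), r(3, 0))
  expect_equal(r(0, 9), r(0, 2))
  df <- random_profiles(4, seed = 1)
  df$prior_fractures <- c(0, 5, 1, 2)
  expect_message(predict_cohort(df, "any", 10, "bmd", co), "clamped")
})

test_that("invalid profiles and horizons are rejected with clear errors", {
  co <- garvan_coefficients()
  expect_error(risk_profile("female", 45), "\\[50, 110\\]")
  expect_error(risk_profile("female", 112), "\\[50, 110\\]")
  expect_error(risk_profile("female", 70, fn_bmd = 2.5), "BMD")
  expect_error(risk_profile("male", 70, weight = 300), "weight")
  expect_error(risk_profile("male", 70, prior_fractures = -1), "non-negative")
  p_no_bmd <- risk_profile("female", 70, weight = 70)
  expect_error(predict_risk(p_no_bmd, "hip", 10, "bmd", co), "missing predictor")
  p_no_wt <- risk_profile("female", 70, tscore = -1)
  expect_error(predict_risk(p_no_wt, "hip", 10, "weight", co), "missing predictor")
  expect_error(predict_risk(p_no_wt, "hip", 7, "bmd", co), "unsupported horizon")
  expect_error(predict_risk(p_no_wt, "vertebral", 10, "bmd", co), "outcome")
})

test_that("cohort prediction matches looping predict_risk row by row", {
  co <- garvan_coefficients()
  df <- random_profiles(100, seed = 99)
  for (variant in c("bmd", "weight")) {
    vec <- predict_cohort(df, "hip", 10, variant, co)
    loop <- vapply(seq_len(nrow(df)), function(i) {
      p <- risk_profile(df$sex[i], df$age[i], fn_bmd = df$fn_bmd[i],
                        weight = df$weight[i],
                        prior_fractures = df$prior_fractures[i],
                        falls_12mo = df$falls_12mo[i])
      predict_risk(p, "hip", 10, variant, co)$probability
    }, numeric(1))
    expect_identical(vec, loop)
  }
  expect_identical(predict_cohort(df[0, ], "hip", 10, "bmd", co), numeric(0))
  one <- predict_cohort(df[3, , drop = FALSE], "hip", 10, "bmd", co)
  expect_length(one, 1L)
})

test_that("cohort prediction rejects invalid records by subject id", {
  co <- garvan_coefficients()
  df <- random_profiles(5, seed = 3)
  df$fn_bmd[2] <- NA
  df$tscore[2] <- NA
  expect_error(predict_cohort(df, "any", 10, "bmd", co), "invalid record 2")
  df2 <- random_profiles(5, seed = 4)
  df2$weight[4] <- NA
  expect_error(predict_cohort(df2, "any", 10, "weight", co), "invalid record 4")
  df3 <- random_profiles(5, seed = 5)
  df3$age[1] <- 40
  expect_error(predict_cohort(df3, "any", 10, "bmd", co), "invalid record 1")
})
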