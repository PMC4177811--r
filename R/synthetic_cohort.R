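# Run expr with a private RNG stream seeded from `seed`, restoring the
# caller's .Random.seed afterwards; with seed = NULL the global stream is
# used (and advanced).
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Configuration for a synthetic elderly screening cohort
#'
#' Defaults emulate an elderly (60+) Norwegian population-based screening
#' cohort of the kind used for external validation of fracture-risk
#' models: women and men in roughly a 55:45 split; age means near 69-70
#' years (SD ~6, truncated to [60, 90]); femoral-neck BMD around 0.83
#' (women) and 0.94 (men) g/cm^2 with SD 0.12-0.13 and a mild decline
#' with age; body weight around 69 and 81 kg correlated with BMD;
#' ~26% of women (10% of men) with at least one prior fracture and ~30%
#' with at least one fall in the past year; constant per-year mortality
#' hazard (optionally increasing with age) and administrative censoring
#' after ~8 years of follow-up.
#'
#' @param n Cohort size.
#' @param sex_fraction_female Proportion of women.
#' @param age Per-sex `c(mean, sd)` of age in years.
#' @param age_range Truncation bounds for age.
#' @param bmd Per-sex `c(mean, sd)` of femoral-neck BMD, g/cm^2.
#' @param bmd_age_slope BMD change per year of age (g/cm^2).
#' @param weight Per-sex `c(mean, sd)` of body weight, kg.
#' @param weight_bmd_cor Correlation between weight and BMD residuals.
#' @param prior_fracture_probs Per-sex probabilities of 0, 1, 2, 3+ prior
#'   fractures (each must sum to 1).
#' @param falls_probs Per-sex probabilities of 0, 1, 2+ falls.
#' @param mortality_rate Per-year death hazard (0 disables mortality).
#' @param mortality_age_slope Log-hazard increase per year of age above
#'   70; 0 gives a constant hazard.
#' @param admin_censor_years Administrative censoring time, years.
#' @param noise_sd_weight_channel Log-odds SD used by
#'   [degrade_predictions()] when emulating a weaker predictor channel.
#' @param seed Default seed for [generate_cohort()].
#' @return Object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n = 2992,
                          sex_fraction_female = 0.547,
                          age = list(female = c(mean = 69.3, sd = 6.3),
                                     male = c(mean = 69.7, sd = 5.7)),
                          age_range = c(60, 90),
                          bmd = list(female = c(mean = 0.83, sd = 0.12),
                                     male = c(mean = 0.94, sd = 0.13)),
                          bmd_age_slope = -0.003,
                          weight = list(female = c(mean = 69.1, sd = 11.8),
                                        male = c(mean = 80.7, sd = 11.7)),
                          weight_bmd_cor = 0.3,
                          prior_fracture_probs = list(
                            female = c(0.742, 0.155, 0.070, 0.033),
                            male = c(0.900, 0.074, 0.020, 0.006)),
                          falls_probs = list(
                            female = c(0.691, 0.296, 0.013),
                            male = c(0.684, 0.299, 0.017)),
                          mortality_rate = 0.02,
                          mortality_age_slope = 0,
                          admin_censor_years = 8.2,
                          noise_sd_weight_channel = 0.6,
                          seed = 42) {
  cfg <- structure(
    list(n = as.integer(n), sex_fraction_female = sex_fraction_female,
         age = age, age_range = age_range, bmd = bmd,
         bmd_age_slope = bmd_age_slope, weight = weight,
         weight_bmd_cor = weight_bmd_cor,
         prior_fracture_probs = prior_fracture_probs,
         falls_probs = falls_probs, mortality_rate = mortality_rate,
         mortality_age_slope = mortality_age_slope,
         admin_censor_years = admin_censor_years,
         noise_sd_weight_channel = noise_sd_weight_channel, seed = seed),
    class = "cohort_config"
  )
  .validate_config(cfg)
  cfg
}

.validate_config <- function(cfg) {
  if (!is.finite(cfg$n) || cfg$n < 1) stop("config: n must be >= 1", call. = FALSE)
  if (cfg$sex_fraction_female < 0 || cfg$sex_fraction_female > 1)
    stop("config: sex_fraction_female must lie in [0, 1]", call. = FALSE)
  for (s in .SEXES) {
    for (field in c("age", "bmd", "weight")) {
      v <- cfg[[field]][[s]]
      if (is.null(v) || length(v) != 2L || any(!is.finite(v)) || v[2] <= 0)
        stop("config: ", field, "[", s, "] must be c(mean, sd) with sd > 0",
             call. = FALSE)
    }
    for (field in c("prior_fracture_probs", "falls_probs")) {
      p <- cfg[[field]][[s]]
      want <- if (field == "prior_fracture_probs") 4L else 3L
      if (is.null(p) || length(p) != want || any(p < 0) ||
          abs(sum(p) - 1) > 1e-6)
        stop("config: ", field, "[", s, "] must be ", want,
             " probabilities summing to 1", call. = FALSE)
    }
  }
  if (cfg$mortality_rate < 0) stop("config: mortality_rate must be >= 0", call. = FALSE)
  if (cfg$admin_censor_years <= 0)
    stop("config: admin_censor_years must be > 0", call. = FALSE)
  if (cfg$noise_sd_weight_channel < 0)
    stop("config: noise_sd_weight_channel must be >= 0", call. = FALSE)
  if (abs(cfg$weight_bmd_cor) >= 1)
    stop("config: weight_bmd_cor must lie in (-1, 1)", call. = FALSE)
  invisible(cfg)
}

#' Read a cohort configuration from YAML
#'
#' Reads a key/value document with any subset of the [cohort_config()]
#' fields and fills the rest with the defaults. The shipped
#' `tromso_like.yaml` (under `extdata`) encodes the default elderly-cohort
#' distributions explicitly.
#'
#' @param path YAML file.
#' @return A `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  doc <- yaml::read_yaml(path)
  # YAML 1.1 parses a bare `n` key as boolean FALSE; map it back
  names(doc)[names(doc) %in% c("FALSE", "no")] <- "n"
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(doc), known)
  if (length(unknown))
    stop("config: unknown field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (f in c("age", "bmd", "weight", "prior_fracture_probs", "falls_probs"))
    if (!is.null(doc[[f]]))
      doc[[f]] <- lapply(doc[[f]], function(v) unlist(v))
  do.call(cohort_config, doc)
}

# inverse-CDF sampling from a truncated normal
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  qnorm(runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd)), mean, sd)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws predictors from the configured distributions, then generates
#' outcomes from the risk model itself: each subject's non-vertebral
#' osteoporotic fracture time follows a constant-hazard process calibrated
#' so that the 10-year cumulative incidence equals that subject's
#' BMD-variant predicted 10-year risk (`lambda = -log(1 - p10) / 10`).
#' Hip events are obtained by thinning: a fracture is a hip fracture with
#' probability `p10_hip / p10_any` (clamped to [0, 1]), so hip events are
#' a subset of any-osteoporotic events and the implied 10-year hip
#' incidence equals the predicted hip risk. An independent exponential
#' death time (hazard `mortality_rate`, optionally scaled by
#' `exp(mortality_age_slope * (age - 70))`) and administrative censoring
#' complete the follow-up: per outcome, follow-up ends at the first of
#' that outcome's fracture, death, or administrative end. A non-hip
#' fracture does not terminate hip follow-up.
#'
#' Everything is drawn from one generator stream governed by a single
#' seed; the same config and seed reproduce the cohort exactly, and the
#' caller's RNG state is left untouched.
#'
#' @param config A [cohort_config()].
#' @param coefficients A `garvan_coefficients` object.
#' @param seed Integer seed (default `config$seed`).
#' @return A cohort `data.frame` in the [read_cohort()] schema.
#' @export
generate_cohort <- function(config = cohort_config(),
                            coefficients = garvan_coefficients(),
                            seed = config$seed) {
  .validate_config(config)
  stopifnot(inherits(coefficients, "garvan_coefficients"))
  n <- config$n
  .with_seed(seed, {
    sex <- ifelse(runif(n) < config$sex_fraction_female, "female", "male")
    age <- numeric(n); bmd <- numeric(n); wt <- numeric(n)
    fx <- numeric(n); falls <- numeric(n)
    for (s in .SEXES) {
      idx <- which(sex == s)
      if (!length(idx)) next
      a <- config$age[[s]]; b <- config$bmd[[s]]; w <- config$weight[[s]]
      age[idx] <- .rtruncnorm(length(idx), a[["mean"]], a[["sd"]],
                              config$age_range[1], config$age_range[2])
      # keep the marginal BMD SD at its configured value despite the age term
      slope_var <- (config$bmd_age_slope * a[["sd"]])^2
      sd_resid <- sqrt(max(b[["sd"]]^2 - slope_var, 1e-8))
      z_bmd <- rnorm(length(idx))
      bmd[idx] <- b[["mean"]] + config$bmd_age_slope * (age[idx] - a[["mean"]]) +
        sd_resid * z_bmd
      rho <- config$weight_bmd_cor
      wt[idx] <- w[["mean"]] + w[["sd"]] *
        (rho * z_bmd + sqrt(1 - rho^2) * rnorm(length(idx)))
      fx[idx] <- sample(0:3, length(idx), replace = TRUE,
                        prob = config$prior_fracture_probs[[s]])
      falls[idx] <- sample(0:2, length(idx), replace = TRUE,
                           prob = config$falls_probs[[s]])
    }
    bmd <- pmin(pmax(bmd, 0.25), 1.9)
    wt <- pmin(pmax(wt, 30), 200)

    cohort <- data.frame(
      subject_id = sprintf("S%05d", seq_len(n)), sex = sex, age = age,
      fn_bmd = bmd, tscore = bmd_to_tscore(bmd, sex, coefficients),
      weight = wt, prior_fractures = fx, falls_12mo = falls,
      stringsAsFactors = FALSE)

    p_any <- predict_cohort(cohort, "any", 10, "bmd", coefficients)
    p_hip <- predict_cohort(cohort, "hip", 10, "bmd", coefficients)

    lambda <- -log(1 - p_any) / 10
    t_frac <- rexp(n) / lambda
    is_hip <- runif(n) < pmin(p_hip / p_any, 1)
    mort <- config$mortality_rate *
      exp(config$mortality_age_slope * (age - 70))
    t_death <- if (config$mortality_rate > 0) rexp(n) / mort else rep(Inf, n)
    cens <- config$admin_censor_years

    t_any <- pmin(t_frac, t_death, cens)
    ev_any <- as.numeric(t_frac <= pmin(t_death, cens))
    t_hipfx <- ifelse(is_hip, t_frac, Inf)
    t_hip <- pmin(t_hipfx, t_death, cens)
    ev_hip <- as.numeric(t_hipfx <= pmin(t_death, cens))

    cohort$time_any <- t_any
    cohort$event_any <- ev_any
    cohort$time_hip <- t_hip
    cohort$event_hip <- ev_hip
    cohort$died <- as.numeric(t_death <= cens & t_death < t_frac)
    cohort
  })
}

#' Degrade a prediction vector with log-odds noise
#'
#' Adds mean-zero Gaussian noise on the log-odds scale
#' (`odds' = odds * exp(e)`, `e ~ N(0, noise_sd^2)`), so perturbed values
#' remain strictly inside (0, 1) without clipping and `noise_sd = 0` is
#' the exact identity. This emulates replacing an informative predictor
#' channel by a noisier surrogate (the body-weight channel standing in
#' for BMD): by the data-processing inequality the degraded predictions
#' can only discriminate worse on average.
#'
#' @param predicted Probabilities strictly inside (0, 1).
#' @param noise_sd Standard deviation of the log-odds perturbation.
#' @param seed Optional seed for a private, reproducible stream.
#' @return Perturbed probability vector of the same length.
#' @export
degrade_predictions <- function(predicted, noise_sd, seed = NULL) {
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || !is.finite(noise_sd) ||
      noise_sd < 0)
    stop("noise_sd must be a single finite value >= 0", call. = FALSE)
  if (any(predicted <= 0 | predicted >= 1))
    stop("predictions must lie strictly inside (0, 1)", call. = FALSE)
  if (noise_sd == 0) return(predicted)
  .with_seed(seed, {
    lo <- log(predicted / (1 - predicted)) + rnorm(length(predicted), 0, noise_sd)
    1 / (1 + exp(-lo))
  })
}
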