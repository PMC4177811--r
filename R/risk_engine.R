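#' Construct and validate a risk profile
#'
#' A risk profile carries one individual's predictors: sex, age in years,
#' femoral-neck BMD (g/cm^2) and/or T-score, body weight (kg), the number
#' of low-trauma fractures since age 50, and the number of falls in the
#' past 12 months. Either BMD measure suffices for the BMD model variant
#' (they are interconverted through the reference constants in the
#' coefficient document); weight is required for the weight variant.
#'
#' Validation is strict: age must lie in [50, 110] (the models were
#' developed and validated in elderly cohorts and are not extrapolated),
#' BMD in (0.2, 2.0) g/cm^2, weight in (25, 250) kg, and the two counts
#' must be finite and non-negative. Counts above the models' top scored
#' category (3+ prior fractures, 2+ falls) are accepted and clamped down
#' to it at evaluation time.
#'
#' @param sex `"female"` or `"male"`.
#' @param age Age in years.
#' @param fn_bmd Femoral-neck BMD in g/cm^2, or `NULL`/`NA`.
#' @param tscore Femoral-neck T-score, or `NULL`/`NA`.
#' @param weight Body weight in kg, or `NULL`/`NA`.
#' @param prior_fractures Count of low-trauma fractures since age 50.
#' @param falls_12mo Count of falls in the past 12 months.
#' @return An object of class `risk_profile`.
#' @export
risk_profile <- function(sex, age, fn_bmd = NULL, tscore = NULL, weight = NULL,
                         prior_fractures = 0, falls_12mo = 0) {
  sex <- .match_sex(sex)
  num_or_na <- function(x) if (is.null(x) || length(x) == 0L) NA_real_ else as.numeric(x[1L])
  p <- structure(
    list(sex = sex, age = as.numeric(age),
         fn_bmd = num_or_na(fn_bmd), tscore = num_or_na(tscore),
         weight = num_or_na(weight),
         prior_fractures = as.numeric(prior_fractures),
         falls_12mo = as.numeric(falls_12mo)),
    class = "risk_profile"
  )
  .validate_profile(p)
  p
}

.validate_profile <- function(p) {
  if (!is.finite(p$age) || p$age < 50 || p$age > 110)
    stop("age must lie within [50, 110] years; got ", p$age, call. = FALSE)
  if (!is.na(p$fn_bmd) && (p$fn_bmd <= 0.2 || p$fn_bmd >= 2.0))
    stop("femoral-neck BMD outside the plausible range (0.2, 2.0) g/cm^2",
         call. = FALSE)
  if (!is.na(p$weight) && (p$weight <= 25 || p$weight >= 250))
    stop("weight outside the plausible range (25, 250) kg", call. = FALSE)
  for (k in c("prior_fractures", "falls_12mo")) {
    v <- p[[k]]
    if (!is.finite(v) || v < 0)
      stop(k, " must be a finite non-negative count", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.risk_profile <- function(x, ...) {
  cat(sprintf("risk_profile: %s, %.0f y", x$sex, x$age))
  if (!is.na(x$tscore)) cat(sprintf(", T-score %.2f", x$tscore))
  if (!is.na(x$fn_bmd)) cat(sprintf(", FN BMD %.3f g/cm2", x$fn_bmd))
  if (!is.na(x$weight)) cat(sprintf(", %.0f kg", x$weight))
  cat(sprintf(", %d prior fx, %d falls\n",
              as.integer(x$prior_fractures), as.integer(x$falls_12mo)))
  invisible(x)
}

# risk = 1 - s0^exp(lp - lp_center), computed as -expm1(e * log(s0)) and
# capped a hair below 1: at extreme (clamped-domain) profiles the survival
# term underflows, and the cap keeps the estimate strictly inside (0, 1).
.risk_from_lp <- function(s0, lp, lp_center) {
  pmin(-expm1(exp(lp - lp_center) * log(s0)), 1 - 1e-12)
}

# Vectorised linear predictor for one (outcome, sex, variant) block.
# Counts above the top category are clamped down; the indices of clamped
# entries are returned so callers can log them.
.linear_predictor <- function(block, variant, age, tscore, weight,
                              prior_fractures, falls) {
  fx_cat <- pmin(floor(prior_fractures), 3)
  fall_cat <- pmin(floor(falls), 2)
  clamped <- which(floor(prior_fractures) > 3 | floor(falls) > 2)
  lp <- block$age * age +
    block$prior_fracture[fx_cat + 1L] +
    block$falls[fall_cat + 1L]
  lp <- lp + if (variant == "bmd") block$tscore * tscore else block$weight * weight
  list(lp = lp, clamped = clamped)
}

#' Predict absolute fracture risk for one profile
#'
#' Evaluates the risk equation for a single individual: the linear
#' predictor over age, BMD T-score (or weight) and the categorical scores
#' for prior fractures and falls is centred and exponentiated against the
#' baseline survival for the requested horizon,
#' `risk = 1 - s0(t)^exp(lp - lp_center)`.
#' Supplying the same bone density as BMD or as T-score gives identical
#' predictions (conversion uses the reference constants in the coefficient
#' document). Only the 5- and 10-year horizons are defined; others are
#' rejected rather than interpolated.
#'
#' @param profile A [risk_profile()].
#' @param outcome `"hip"` or `"any"` (non-vertebral osteoporotic).
#' @param horizon Horizon in years: 5 or 10.
#' @param variant `"bmd"` or `"weight"`.
#' @param coefficients A `garvan_coefficients` object.
#' @return An object of class `risk_estimate` with fields `probability`,
#'   `outcome`, `horizon`, `variant` and `profile`.
#' @export
predict_risk <- function(profile, outcome, horizon, variant = c("bmd", "weight"),
                         coefficients = garvan_coefficients()) {
  stopifnot(inherits(profile, "risk_profile"))
  outcome <- .match_outcome(outcome)
  variant <- match.arg(variant)
  if (length(horizon) != 1L || !horizon %in% .HORIZONS)
    stop("unsupported horizon: ", paste(horizon, collapse = ","),
         "; the models define 5- and 10-year risks only", call. = FALSE)
  .validate_profile(profile)

  tsc <- profile$tscore
  if (variant == "bmd") {
    if (is.na(tsc) && is.na(profile$fn_bmd))
      stop("missing predictor: the BMD variant needs femoral-neck BMD or T-score",
           call. = FALSE)
    if (is.na(tsc))
      tsc <- bmd_to_tscore(profile$fn_bmd, profile$sex, coefficients)
  } else if (is.na(profile$weight)) {
    stop("missing predictor: the weight variant needs body weight", call. = FALSE)
  }

  block <- coefficients$blocks[[.block_key(outcome, profile$sex, variant)]]
  lp <- .linear_predictor(block, variant, profile$age, tsc, profile$weight,
                          profile$prior_fractures, profile$falls_12mo)
  s0 <- block$s0[[as.character(horizon)]]
  prob <- .risk_from_lp(s0, lp$lp, block$lp_center)
  structure(
    list(probability = prob, outcome = outcome, horizon = horizon,
         variant = variant, profile = profile,
         clamped = length(lp$clamped) > 0L),
    class = "risk_estimate"
  )
}

#' @export
print.risk_estimate <- function(x, ...) {
  cat(sprintf("%d-year %s fracture risk (%s model): %.1f%%\n",
              x$horizon,
              if (x$outcome == "hip") "hip" else "non-vertebral osteoporotic",
              x$variant, 100 * x$probability))
  invisible(x)
}

#' Predict absolute fracture risk for a whole cohort
#'
#' Vectorised evaluation over a cohort table (one row per subject, the
#' [read_cohort()] schema). The result is order-preserving and element `i`
#' equals [predict_risk()] on row `i`. Any row that cannot yield a valid
#' profile for the requested variant (missing predictor, out-of-range
#' value) aborts the whole call with an error naming the subject; rows are
#' never silently skipped. Counts above the top scored category are
#' clamped, and a message reports how many rows were affected.
#'
#' @param records A cohort `data.frame` (see [read_cohort()]).
#' @param outcome,horizon,variant,coefficients As in [predict_risk()].
#' @return Numeric vector of probabilities, one per row of `records`.
#' @export
predict_cohort <- function(records, outcome, horizon, variant = c("bmd", "weight"),
                           coefficients = garvan_coefficients()) {
  outcome <- .match_outcome(outcome)
  variant <- match.arg(variant)
  if (length(horizon) != 1L || !horizon %in% .HORIZONS)
    stop("unsupported horizon: ", paste(horizon, collapse = ","), call. = FALSE)
  n <- nrow(records)
  if (is.null(n)) stop("records must be a data.frame", call. = FALSE)
  if (n == 0L) return(numeric(0))

  ids <- if ("subject_id" %in% names(records)) as.character(records$subject_id)
         else as.character(seq_len(n))
  sex <- .match_sex(records$sex)
  age <- as.numeric(records$age)
  tsc <- if ("tscore" %in% names(records)) as.numeric(records$tscore) else rep(NA_real_, n)
  bmd <- if ("fn_bmd" %in% names(records)) as.numeric(records$fn_bmd) else rep(NA_real_, n)
  wt <- if ("weight" %in% names(records)) as.numeric(records$weight) else rep(NA_real_, n)
  fx <- as.numeric(records$prior_fractures)
  falls <- as.numeric(records$falls_12mo)

  bad_age <- which(!is.finite(age) | age < 50 | age > 110)
  if (length(bad_age))
    stop("invalid record ", ids[bad_age[1L]], ": age outside [50, 110]", call. = FALSE)
  bad_cnt <- which(!is.finite(fx) | fx < 0 | !is.finite(falls) | falls < 0)
  if (length(bad_cnt))
    stop("invalid record ", ids[bad_cnt[1L]], ": counts must be finite and >= 0",
         call. = FALSE)

  if (variant == "bmd") {
    fill <- is.na(tsc)
    if (any(fill & !is.na(bmd))) {
      idx <- which(fill & !is.na(bmd))
      tsc[idx] <- bmd_to_tscore(bmd[idx], sex[idx], coefficients)
    }
    miss <- which(is.na(tsc))
    if (length(miss))
      stop("invalid record ", ids[miss[1L]],
           ": BMD variant needs femoral-neck BMD or T-score (",
           length(miss), " record(s) affected)", call. = FALSE)
  } else {
    miss <- which(is.na(wt))
    if (length(miss))
      stop("invalid record ", ids[miss[1L]],
           ": weight variant needs body weight (",
           length(miss), " record(s) affected)", call. = FALSE)
    bad_wt <- which(wt <= 25 | wt >= 250)
    if (length(bad_wt))
      stop("invalid record ", ids[bad_wt[1L]], ": weight outside (25, 250) kg",
           call. = FALSE)
  }

  out <- numeric(n)
  clamped_all <- integer(0)
  for (s in .SEXES) {
    idx <- which(sex == s)
    if (!length(idx)) next
    block <- coefficients$blocks[[.block_key(outcome, s, variant)]]
    lp <- .linear_predictor(block, variant, age[idx], tsc[idx], wt[idx],
                            fx[idx], falls[idx])
    s0 <- block$s0[[as.character(horizon)]]
    out[idx] <- .risk_from_lp(s0, lp$lp, block$lp_center)
    clamped_all <- c(clamped_all, idx[lp$clamped])
  }
  if (length(clamped_all))
    message(length(clamped_all),
            " record(s) had counts above the top scored category and were clamped: ",
            paste(utils::head(ids[sort(clamped_all)], 5L), collapse = ", "),
            if (length(clamped_all) > 5L) ", ..." else "")
  out
}
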