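#' Predicted-versus-observed calibration across quantile groups
#'
#' Groups a cohort by empirical quantiles of predicted risk (quintiles for
#' non-vertebral osteoporotic fracture, quartile-style 4 groups for hip,
#' by convention of the validation literature; any `n_groups >= 2` is
#' accepted) and compares each group's mean predicted risk with its
#' observed cumulative incidence at the horizon. The observed risk is the
#' Kaplan-Meier complement `1 - S(horizon)` within the group — death and
#' administrative end of follow-up are treated as censoring, which matters
#' when mean follow-up is shorter than the prediction horizon — with a
#' crude event-proportion option for fully observed cohorts.
#'
#' Ties at a quantile cut-off are assigned to the lower group. If the
#' predictions carry too few distinct values to form `n_groups` groups
#' (e.g. all identical), a degenerate-grouping error is raised advising a
#' smaller `n_groups`.
#'
#' @param predicted Predicted risks in (0, 1).
#' @param followup_years Per-subject follow-up time for the outcome.
#' @param events 0/1 event indicator for the outcome.
#' @param n_groups Number of quantile groups (default 5).
#' @param horizon Horizon in years at which observed risk is evaluated.
#' @param method `"km"` (Kaplan-Meier) or `"crude"` (event proportion).
#' @param conf_level Confidence level for the observed-risk interval.
#' @return Object of class `calibration_table`: a `data.frame` with one
#'   row per group (`group`, `n`, `n_events`, `mean_predicted`,
#'   `observed_risk`, `observed_ci_low`, `observed_ci_high`) and
#'   attributes `cutoffs` (the interior quantile cut-offs) and `horizon`.
#' @export
calibration_table <- function(predicted, followup_years, events, n_groups = 5,
                              horizon = 10, method = c("km", "crude"),
                              conf_level = 0.95) {
  method <- match.arg(method)
  n <- length(predicted)
  stopifnot(length(followup_years) == n, length(events) == n)
  if (n_groups < 2) stop("n_groups must be at least 2", call. = FALSE)
  if (n <= n_groups) stop("cohort must be larger than n_groups", call. = FALSE)
  breaks <- quantile(predicted, probs = seq(0, 1, length.out = n_groups + 1),
                     names = FALSE)
  if (anyDuplicated(breaks))
    stop("degenerate grouping: predictions have too few distinct values to ",
         "form ", n_groups, " quantile groups; reduce n_groups", call. = FALSE)
  group <- cut(predicted, breaks = breaks, include.lowest = TRUE,
               labels = FALSE, right = TRUE)

  rows <- lapply(seq_len(n_groups), function(g) {
    idx <- group == g
    ng <- sum(idx)
    if (method == "km") {
      fit <- survival::survfit(
        survival::Surv(followup_years[idx], events[idx]) ~ 1,
        conf.int = conf_level)
      sm <- summary(fit, times = horizon, extend = TRUE)
      obs <- 1 - sm$surv
      lo <- 1 - sm$upper
      hi <- 1 - sm$lower
      if (is.na(lo)) lo <- 0
      if (is.na(hi)) hi <- 1
    } else {
      within <- events[idx] == 1 & followup_years[idx] <= horizon
      obs <- mean(within)
      ci <- stats::binom.test(sum(within), ng)$conf.int
      lo <- ci[1]; hi <- ci[2]
    }
    data.frame(group = g, n = ng, n_events = sum(events[idx] == 1),
               mean_predicted = mean(predicted[idx]), observed_risk = obs,
               observed_ci_low = lo, observed_ci_high = hi)
  })
  out <- do.call(rbind, rows)
  attr(out, "cutoffs") <- breaks[2:n_groups]
  attr(out, "horizon") <- horizon
  attr(out, "method") <- method
  class(out) <- c("calibration_table", "data.frame")
  out
}

#' @export
print.calibration_table <- function(x, digits = 3, ...) {
  cat(sprintf("Calibration at %g years (%s observed risk); cut-offs (%%): %s\n",
              attr(x, "horizon"), attr(x, "method"),
              paste(sprintf("%.1f", 100 * attr(x, "cutoffs")), collapse = ", ")))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Ratio of predicted risk between fracture and non-fracture subjects
#'
#' Computes the geometric-mean ratio of predicted risk in subjects who
#' fractured versus those who did not:
#' `exp(mean(log p | event) - mean(log p | no event))`, with a Welch-type
#' two-sample confidence interval on the log scale, back-transformed. A
#' well-discriminating model gives a ratio well above 1; the ratio is
#' invariant to rescaling all predictions by a constant.
#'
#' @param predicted Predicted risks, all strictly positive.
#' @param events 0/1 event indicator.
#' @param conf_level Confidence level.
#' @return Object of class `risk_ratio_result`: `ratio`, `ci_low`,
#'   `ci_high`, `n_fracture`, `n_nonfracture`.
#' @export
predicted_risk_ratio <- function(predicted, events, conf_level = 0.95) {
  if (length(predicted) != length(events))
    stop("predicted and events must have equal length", call. = FALSE)
  if (any(predicted <= 0))
    stop("all predictions must be strictly positive", call. = FALSE)
  lp <- log(predicted)
  l1 <- lp[events == 1]; l0 <- lp[events == 0]
  n1 <- length(l1); n0 <- length(l0)
  if (n1 == 0L || n0 == 0L)
    stop("degenerate outcome: both groups must be non-empty", call. = FALSE)
  d <- mean(l1) - mean(l0)
  if (n1 > 1 && n0 > 1) {
    v1 <- var(l1) / n1; v0 <- var(l0) / n0
    se <- sqrt(v1 + v0)
    df <- if (se == 0) Inf else (v1 + v0)^2 / (v1^2 / (n1 - 1) + v0^2 / (n0 - 1))
    q <- qt(1 - (1 - conf_level) / 2, df)
    ci <- exp(d + c(-1, 1) * q * se)
  } else {
    ci <- c(NA_real_, NA_real_)
  }
  structure(
    list(ratio = exp(d), ci_low = ci[1], ci_high = ci[2],
         n_fracture = n1, n_nonfracture = n0, conf_level = conf_level),
    class = "risk_ratio_result"
  )
}

#' @export
print.risk_ratio_result <- function(x, ...) {
  cat(sprintf("predicted-risk ratio (fracture / non-fracture): %.2f (%d%% CI %.2f-%.2f)\n",
              x$ratio, round(100 * x$conf_level), x$ci_low, x$ci_high))
  invisible(x)
}
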