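# Placement values for the Mann-Whitney AUC (DeLong's pseudo-values).
# For event scores X (m of them) and non-event scores Y (n of them):
#   V10[i] = P-hat(X_i beats a random Y), V01[j] = P-hat(a random X beats Y_j),
# ties credited 1/2. Computed from midranks:
#   V10[i] = (rank of X_i among all - rank among events) / n
#   V01[j] = 1 - (rank of Y_j among all - rank among non-events) / m
.placements <- function(pred, events) {
  x <- pred[events == 1]
  y <- pred[events == 0]
  m <- length(x); n <- length(y)
  r_all <- rank(c(x, y), ties.method = "average")
  v10 <- (r_all[seq_len(m)] - rank(x, ties.method = "average")) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(y, ties.method = "average")) / m
  list(v10 = v10, v01 = v01, m = m, n = n)
}

#' ROC area under the curve with DeLong standard error
#'
#' The AUC is the probability that a randomly chosen subject who fractured
#' receives a higher predicted risk than a randomly chosen subject who did
#' not, with ties credited 1/2 (the Mann-Whitney convention). The standard
#' error uses DeLong's placement-value estimator and the confidence
#' interval is normal on the AUC scale, truncated to [0, 1] (a logit-scale
#' interval is available for AUCs near the boundary).
#'
#' The default outcome is the binary "suffered a fracture during follow-up"
#' indicator. For horizon-restricted analyses, filter the cohort first with
#' [restrict_to_horizon()], which keeps events within the horizon as cases
#' and subjects followed past the horizon as controls, excluding subjects
#' censored early — the two choices are reported side by side because
#' neither is canonical for externally validating a fixed-horizon model.
#'
#' @param predicted Numeric vector of predicted risks (any monotone score
#'   works: the AUC is rank-invariant).
#' @param events 0/1 vector of the same length.
#' @param conf_level Confidence level.
#' @param ci_scale `"auc"` (normal, truncated) or `"logit"`.
#' @return Object of class `roc_result`: list with `auc`, `se`, `ci_low`,
#'   `ci_high`, `n_events`, `n_nonevents`.
#' @export
roc_auc <- function(predicted, events, conf_level = 0.95,
                    ci_scale = c("auc", "logit")) {
  ci_scale <- match.arg(ci_scale)
  if (length(predicted) != length(events))
    stop("predicted and events must have equal length", call. = FALSE)
  if (anyNA(predicted) || anyNA(events))
    stop("missing values in predictions or events", call. = FALSE)
  if (!all(events %in% c(0, 1)))
    stop("events must be 0/1", call. = FALSE)
  m <- sum(events == 1); n <- sum(events == 0)
  if (m == 0L || n == 0L)
    stop("degenerate outcome: need at least one event and one non-event",
         call. = FALSE)
  pl <- .placements(predicted, events)
  auc <- mean(pl$v10)
  s10 <- if (m > 1) var(pl$v10) else 0
  s01 <- if (n > 1) var(pl$v01) else 0
  se <- sqrt(s10 / m + s01 / n)
  z <- qnorm(1 - (1 - conf_level) / 2)
  if (ci_scale == "auc") {
    ci <- pmin(1, pmax(0, auc + c(-1, 1) * z * se))
  } else {
    if (auc <= 0 || auc >= 1 || se == 0) {
      ci <- c(auc, auc)
    } else {
      lg <- log(auc / (1 - auc))
      se_lg <- se / (auc * (1 - auc))
      ci <- stats::plogis(lg + c(-1, 1) * z * se_lg)
    }
  }
  structure(
    list(auc = auc, se = se, ci_low = ci[1], ci_high = ci[2],
         n_events = m, n_nonevents = n, conf_level = conf_level),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (SE %.3f, %d%% CI %.3f-%.3f; %d events / %d non-events)\n",
              x$auc, x$se, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$n_events, x$n_nonevents))
  invisible(x)
}

#' Paired comparison of two AUCs (DeLong test)
#'
#' Compares the AUCs of two prediction vectors on the same subjects (e.g.
#' the BMD-variant versus the weight-variant model). The variance of the
#' AUC difference accounts for the pairing through the covariance of the
#' DeLong placement values; the p-value is two-sided normal.
#'
#' @param predicted_a,predicted_b Paired prediction vectors.
#' @param events 0/1 outcome vector.
#' @return Object of class `auc_comparison`: `auc_a`, `auc_b`, `delta`
#'   (`auc_a - auc_b`), `se_delta`, `z`, `p_value`.
#' @export
compare_auc <- function(predicted_a, predicted_b, events) {
  if (length(predicted_a) != length(predicted_b))
    stop("pairing error: prediction vectors differ in length", call. = FALSE)
  if (length(predicted_a) != length(events))
    stop("pairing error: predictions and events differ in length", call. = FALSE)
  m <- sum(events == 1); n <- sum(events == 0)
  if (m == 0L || n == 0L)
    stop("degenerate outcome: need at least one event and one non-event",
         call. = FALSE)
  pa <- .placements(predicted_a, events)
  pb <- .placements(predicted_b, events)
  auc_a <- mean(pa$v10); auc_b <- mean(pb$v10)
  d10 <- pa$v10 - pb$v10
  d01 <- pa$v01 - pb$v01
  v <- (if (m > 1) var(d10) else 0) / m + (if (n > 1) var(d01) else 0) / n
  se <- sqrt(v)
  delta <- auc_a - auc_b
  if (se == 0) {
    z <- 0; p <- 1
  } else {
    z <- delta / se
    p <- 2 * pnorm(-abs(z))
  }
  structure(
    list(auc_a = auc_a, auc_b = auc_b, delta = delta, se_delta = se,
         z = z, p_value = p, n_events = m, n_nonevents = n),
    class = "auc_comparison"
  )
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf("AUC %.3f vs %.3f; difference %+.3f (SE %.3f), z = %.2f, p = %.3g\n",
              x$auc_a, x$auc_b, x$delta, x$se_delta, x$z, x$p_value))
  invisible(x)
}

#' Restrict a cohort to a fixed-horizon binary outcome
#'
#' Keeps subjects who fractured within `horizon` years (cases) and
#' subjects followed at least `horizon` years without that fracture
#' (controls); subjects censored before the horizon without an event are
#' dropped, since their horizon status is unknown.
#'
#' @param records Cohort `data.frame`.
#' @param outcome `"hip"` or `"any"`.
#' @param horizon Years.
#' @return The subset with an added 0/1 column `event_within_horizon`.
#' @export
restrict_to_horizon <- function(records, outcome, horizon) {
  outcome <- .match_outcome(outcome)
  ev <- records[[paste0("event_", outcome)]]
  tt <- records[[paste0("time_", outcome)]]
  case <- ev == 1 & tt <= horizon
  control <- tt >= horizon & !(ev == 1 & tt <= horizon)
  out <- records[case | control, , drop = FALSE]
  out$event_within_horizon <- as.numeric(case[case | control])
  out
}

#' Discrimination table across strata
#'
#' Convenience wrapper computing the AUC of every (sex, outcome, variant,
#' horizon) combination on a cohort, the layout in which external
#' validations report discrimination.
#'
#' @param records Cohort `data.frame`.
#' @param coefficients A `garvan_coefficients` object.
#' @param horizons Horizons to include.
#' @return `data.frame` with one row per stratum and columns `sex`,
#'   `outcome`, `variant`, `horizon`, `auc`, `se`, `ci_low`, `ci_high`,
#'   `n_events`, `n_nonevents`.
#' @export
discrimination_table <- function(records, coefficients = garvan_coefficients(),
                                 horizons = c(5, 10)) {
  grid <- expand.grid(sex = .SEXES, outcome = .OUTCOMES, variant = .VARIANTS,
                      horizon = horizons, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sub <- records[records$sex == grid$sex[i], , drop = FALSE]
    pred <- predict_cohort(sub, grid$outcome[i], grid$horizon[i],
                           grid$variant[i], coefficients)
    r <- roc_auc(pred, sub[[paste0("event_", grid$outcome[i])]])
    cbind(grid[i, , drop = FALSE],
          data.frame(auc = r$auc, se = r$se, ci_low = r$ci_low,
                     ci_high = r$ci_high, n_events = r$n_events,
                     n_nonevents = r$n_nonevents))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
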