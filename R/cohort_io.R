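#' Canonical cohort column schema
#'
#' Cohort tables are delimited text with a header row, one row per subject.
#' The canonical columns are: `subject_id`; the predictor fields `sex`,
#' `age`, `fn_bmd`, `tscore`, `weight`, `prior_fractures`, `falls_12mo`;
#' per-outcome follow-up `time_any`/`event_any` and `time_hip`/`event_hip`
#' (years to first event of that outcome or censoring, and the 0/1 event
#' indicator — the two outcomes carry separate follow-up because censoring
#' at first fracture differs between them); and `died` (0/1). A schema
#' configuration maps canonical names to the file's column names; the
#' default is the identity mapping.
#'
#' @param ... Named overrides, e.g. `cohort_schema(age = "baseline_age")`.
#' @return Named character vector mapping canonical names to file columns.
#' @export
cohort_schema <- function(...) {
  schema <- c(subject_id = "subject_id", sex = "sex", age = "age",
              fn_bmd = "fn_bmd", tscore = "tscore", weight = "weight",
              prior_fractures = "prior_fractures", falls_12mo = "falls_12mo",
              time_any = "time_any", event_any = "event_any",
              time_hip = "time_hip", event_hip = "event_hip", died = "died")
  over <- c(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(schema))
    if (length(unknown))
      stop("unknown schema field(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    schema[names(over)] <- over
  }
  schema
}

.PREDICTOR_COLS <- c("fn_bmd", "tscore", "weight")

#' Read a cohort table
#'
#' Reads a delimited-text cohort table (comma-separated by default, header
#' row required, period decimal mark, UTF-8) and validates it row by row.
#' Follow-up times must be strictly positive and event/death indicators
#' must be 0/1; violations raise an error naming the subject. The
#' predictor columns `fn_bmd`, `tscore` and `weight` may contain missing
#' cells — subjects lacking a predictor are rejected only when a
#' prediction is requested under the variant that needs it (mirroring the
#' upstream exclusion of subjects with incomplete risk-factor history),
#' and [predictor_completeness()] reports how many rows each variant would
#' exclude.
#'
#' @param path Path to the delimited file.
#' @param schema A mapping from [cohort_schema()].
#' @param sep Field separator (default `","`).
#' @return A `data.frame` with canonical column names, one row per subject.
#' @export
read_cohort <- function(path, schema = cohort_schema(), sep = ",") {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  check.names = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(unname(schema), names(raw))
  if (length(missing_cols))
    stop("schema error: mapped column(s) absent from file: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- raw[unname(schema)]
  names(df) <- names(schema)
  .validate_cohort(df)
}

.validate_cohort <- function(df) {
  n <- nrow(df)
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id values in cohort", call. = FALSE)
  df$sex <- .match_sex(df$sex)
  num_cols <- c("age", .PREDICTOR_COLS, "prior_fractures", "falls_12mo",
                "time_any", "event_any", "time_hip", "event_hip", "died")
  for (col in num_cols) {
    v <- df[[col]]
    if (is.character(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v) & nzchar(trimws(v)))
      if (length(bad))
        stop("subject ", df$subject_id[bad[1L]], ": unparseable value '",
             v[bad[1L]], "' in column ", col, call. = FALSE)
      v <- conv
    }
    df[[col]] <- as.numeric(v)
  }
  for (col in c("time_any", "time_hip")) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] <= 0)
    if (length(bad))
      stop("subject ", df$subject_id[bad[1L]], ": follow-up time ", col,
           " must be > 0", call. = FALSE)
  }
  for (col in c("event_any", "event_hip", "died")) {
    bad <- which(!df[[col]] %in% c(0, 1))
    if (length(bad))
      stop("subject ", df$subject_id[bad[1L]], ": ", col, " must be 0 or 1",
           call. = FALSE)
  }
  bad <- which(df$event_hip == 1 & df$event_any == 0)
  if (length(bad))
    stop("subject ", df$subject_id[bad[1L]],
         ": hip fractures must be a subset of any-osteoporotic fractures",
         call. = FALSE)
  df
}

#' @rdname read_cohort
#' @param cohort A cohort `data.frame`.
#' @export
write_cohort <- function(cohort, path, sep = ",") {
  write.table(cohort, path, sep = sep, row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Count rows each model variant would exclude
#'
#' @param cohort A cohort `data.frame`.
#' @return Named integer vector: rows lacking the predictors of the BMD
#'   variant and of the weight variant.
#' @export
predictor_completeness <- function(cohort) {
  c(bmd = sum(is.na(cohort$fn_bmd) & is.na(cohort$tscore)),
    weight = sum(is.na(cohort$weight)))
}

#' Summarise follow-up for one outcome
#'
#' Totals subjects, first incident fractures of the requested outcome, and
#' person-years (the sum of per-subject follow-up for that outcome).
#'
#' @param records A cohort `data.frame`.
#' @param outcome `"hip"` or `"any"`.
#' @return Object of class `followup_summary`: list with `n_subjects`,
#'   `n_events`, `person_years`, `outcome`.
#' @export
summarize_followup <- function(records, outcome) {
  outcome <- .match_outcome(outcome)
  if (is.null(nrow(records)) || nrow(records) == 0L)
    stop("empty cohort: nothing to summarise", call. = FALSE)
  ev <- records[[paste0("event_", outcome)]]
  tt <- records[[paste0("time_", outcome)]]
  structure(
    list(n_subjects = nrow(records), n_events = sum(ev == 1),
         person_years = sum(tt), outcome = outcome),
    class = "followup_summary"
  )
}

#' @export
print.followup_summary <- function(x, ...) {
  cat(sprintf("%s fracture follow-up: %d subjects, %d first events, %.1f person-years\n",
              if (x$outcome == "hip") "hip" else "non-vertebral osteoporotic",
              x$n_subjects, x$n_events, x$person_years))
  invisible(x)
}

#' Incidence rate per 1000 person-years
#'
#' `rate = 1000 * events / person_years`, with a confidence interval by the
#' exact Poisson (gamma-quantile) method by default:
#' lower `= qgamma(a/2, events) / py`, upper `= qgamma(1 - a/2, events + 1)
#' / py` (lower bound 0 when there are no events). A log-normal
#' approximation (`rate * exp(±z / sqrt(events))`) is available; the exact
#' method behaves correctly at small counts.
#'
#' @param summary A `followup_summary`, or a list with `n_events` and
#'   `person_years`.
#' @param ci_method `"exact"` (Poisson) or `"lognormal"`.
#' @param conf_level Confidence level (default 0.95).
#' @param per Denominator scale (default 1000 person-years).
#' @return Object of class `incidence_rate`: list with `rate`, `ci_low`,
#'   `ci_high`, `n_events`, `person_years`, `method`, `per`.
#' @export
incidence_rate <- function(summary, ci_method = c("exact", "lognormal"),
                           conf_level = 0.95, per = 1000) {
  ci_method <- match.arg(ci_method)
  ev <- summary$n_events
  py <- summary$person_years
  if (!is.finite(py) || py <= 0)
    stop("person_years must be > 0", call. = FALSE)
  if (!is.finite(ev) || ev < 0) stop("n_events must be >= 0", call. = FALSE)
  a <- 1 - conf_level
  rate <- per * ev / py
  if (ci_method == "exact") {
    lo <- if (ev == 0) 0 else per * qgamma(a / 2, ev) / py
    hi <- per * qgamma(1 - a / 2, ev + 1) / py
  } else {
    if (ev == 0) stop("log-normal interval undefined at zero events; use 'exact'",
                      call. = FALSE)
    z <- qnorm(1 - a / 2)
    lo <- rate * exp(-z / sqrt(ev))
    hi <- rate * exp(z / sqrt(ev))
  }
  structure(
    list(rate = rate, ci_low = lo, ci_high = hi, n_events = ev,
         person_years = py, method = ci_method, per = per,
         conf_level = conf_level),
    class = "incidence_rate"
  )
}

#' @export
print.incidence_rate <- function(x, ...) {
  cat(sprintf("%.1f per %d person-years (%d%% CI %.1f-%.1f, %s)\n",
              x$rate, x$per, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$method))
  invisible(x)
}
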