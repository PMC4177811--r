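.risk_categories <- function(pred, thresholds) {
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing", call. = FALSE)
  findInterval(pred, thresholds, left.open = TRUE) + 1L
}

#' Cross-tabulate risk categories under two models
#'
#' Assigns every subject a risk category under a reference and a
#' comparison model using the supplied thresholds, and cross-tabulates the
#' two assignments separately for subjects with and without fracture. Each
#' model may use its own threshold vector (the quartiles of its own
#' predicted risks, the convention for model-specific risk groups) or both
#' may share one.
#'
#' @param pred_reference,pred_comparison Paired prediction vectors.
#' @param events 0/1 event indicator.
#' @param thresholds Threshold vector for the reference model (strictly
#'   increasing category boundaries).
#' @param thresholds_comparison Thresholds for the comparison model;
#'   defaults to `thresholds` (shared-threshold mode).
#' @return Object of class `reclassification_table`: list with `event` and
#'   `nonevent` contingency matrices (reference category in rows,
#'   comparison category in columns) and the threshold vectors.
#' @export
reclassification_table <- function(pred_reference, pred_comparison, events,
                                   thresholds,
                                   thresholds_comparison = thresholds) {
  n <- length(pred_reference)
  if (length(pred_comparison) != n || length(events) != n)
    stop("pairing error: vectors must have equal length", call. = FALSE)
  cat_ref <- .risk_categories(pred_reference, thresholds)
  cat_cmp <- .risk_categories(pred_comparison, thresholds_comparison)
  k_ref <- length(thresholds) + 1L
  k_cmp <- length(thresholds_comparison) + 1L
  tab <- function(sel) {
    t0 <- table(factor(cat_ref[sel], levels = seq_len(k_ref)),
                factor(cat_cmp[sel], levels = seq_len(k_cmp)))
    m <- matrix(as.integer(t0), nrow = k_ref, ncol = k_cmp,
                dimnames = list(reference = rownames(t0), comparison = colnames(t0)))
    m
  }
  structure(
    list(event = tab(events == 1), nonevent = tab(events == 0),
         thresholds = thresholds, thresholds_comparison = thresholds_comparison),
    class = "reclassification_table"
  )
}

#' @export
print.reclassification_table <- function(x, ...) {
  cat("Reclassification cross-tabulation (rows: reference, cols: comparison)\n")
  cat("Subjects with fracture:\n"); print(x$event)
  cat("Subjects without fracture:\n"); print(x$nonevent)
  invisible(x)
}

.nri_components <- function(p_up, p_down, n) {
  nri <- p_up - p_down
  se <- sqrt((p_up + p_down - nri^2) / n)
  list(nri = nri, se = se)
}

.nri_result <- function(ev, ne, n_events, n_nonevents, mode) {
  nri_event <- ev$nri
  nri_nonevent <- -ne$nri           # correct direction for non-events is DOWN
  nri_overall <- nri_event + nri_nonevent
  se_overall <- sqrt(ev$se^2 + ne$se^2)
  pval <- function(x, s) {
    if (s == 0) return(if (x == 0) 1 else 0)
    2 * pnorm(-abs(x / s))
  }
  structure(
    list(nri_event = nri_event, nri_nonevent = nri_nonevent,
         nri_overall = nri_overall,
         se_event = ev$se, se_nonevent = ne$se, se_overall = se_overall,
         p_event = pval(nri_event, ev$se),
         p_nonevent = pval(nri_nonevent, ne$se),
         p_overall = pval(nri_overall, se_overall),
         n_events = n_events, n_nonevents = n_nonevents,
         threshold_mode = mode,
         direction_convention = paste(
           "positive = comparison model classifies better than reference")),
    class = "nri_result"
  )
}

#' Net reclassification improvement (categorical, Pencina)
#'
#' Compares how a comparison model reclassifies subjects relative to a
#' reference model across risk categories. Upward moves are correct for
#' subjects who fractured, downward moves for subjects who did not:
#' `nri_event = P(up | event) - P(down | event)`,
#' `nri_nonevent = P(down | non-event) - P(up | non-event)`,
#' `nri_overall = nri_event + nri_nonevent`.
#' Standard errors use Pencina's asymptotic multinomial variance and
#' p-values are two-sided normal. The sign convention — positive means the
#' comparison model performs better — is carried in the result and printed
#' with it.
#'
#' By default each model is categorised by the quartiles of its own
#' predicted risks (`threshold_mode = "model_specific"`); pass explicit
#' `thresholds` for shared cut-offs. Components are invariant under any
#' strictly monotone transform applied jointly to a model's predictions
#' and its thresholds, and swapping reference and comparison negates all
#' three indices exactly.
#'
#' @param pred_reference,pred_comparison Paired prediction vectors (e.g.
#'   BMD-variant and weight-variant predicted risks).
#' @param events 0/1 event indicator.
#' @param thresholds Optional shared threshold vector; when `NULL`, each
#'   model uses its own prediction quartiles.
#' @return Object of class `nri_result`; see fields above.
#' @export
nri <- function(pred_reference, pred_comparison, events, thresholds = NULL) {
  n <- length(pred_reference)
  if (length(pred_comparison) != n || length(events) != n)
    stop("pairing error: vectors must have equal length", call. = FALSE)
  n1 <- sum(events == 1); n0 <- sum(events == 0)
  if (n1 == 0L || n0 == 0L)
    stop("degenerate outcome: need at least one event and one non-event",
         call. = FALSE)
  if (is.null(thresholds)) {
    mode <- "model_specific"
    thr_ref <- unname(quantile(pred_reference, c(0.25, 0.5, 0.75)))
    thr_cmp <- unname(quantile(pred_comparison, c(0.25, 0.5, 0.75)))
    thr_ref <- unique(thr_ref); thr_cmp <- unique(thr_cmp)
  } else {
    mode <- "shared"
    thr_ref <- thresholds; thr_cmp <- thresholds
  }
  cat_ref <- .risk_categories(pred_reference, thr_ref)
  cat_cmp <- .risk_categories(pred_comparison, thr_cmp)
  up <- cat_cmp > cat_ref
  down <- cat_cmp < cat_ref
  ev <- .nri_components(mean(up[events == 1]), mean(down[events == 1]), n1)
  ne <- .nri_components(mean(up[events == 0]), mean(down[events == 0]), n0)
  .nri_result(ev, ne, n1, n0, mode)
}

#' NRI from a reclassification cross-tabulation
#'
#' Computes the same indices as [nri()] directly from the contingency
#' matrices of a [reclassification_table()], providing an independent path
#' to the same quantity: the two must agree exactly when the table was
#' built from the same vectors and thresholds.
#'
#' @param table A `reclassification_table`.
#' @return An `nri_result`.
#' @export
nri_from_table <- function(table) {
  stopifnot(inherits(table, "reclassification_table"))
  moves <- function(m) {
    n <- sum(m)
    ridx <- row(m); cidx <- col(m)
    list(up = sum(m[cidx > ridx]) / n, down = sum(m[cidx < ridx]) / n, n = n)
  }
  e <- moves(table$event); v <- moves(table$nonevent)
  ev <- .nri_components(e$up, e$down, e$n)
  ne <- .nri_components(v$up, v$down, v$n)
  .nri_result(ev, ne, e$n, v$n, "from_table")
}

#' @export
print.nri_result <- function(x, ...) {
  cat("Net reclassification improvement (", x$direction_convention, ")\n", sep = "")
  tab <- data.frame(
    index = c(x$nri_event, x$nri_nonevent, x$nri_overall),
    SE = c(x$se_event, x$se_nonevent, x$se_overall),
    p = c(x$p_event, x$p_nonevent, x$p_overall),
    row.names = c("NRI for fracture", "NRI for non-fracture", "NRI overall"))
  print(round(tab, 4))
  invisible(x)
}
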