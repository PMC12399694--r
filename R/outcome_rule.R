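# Two-threshold decision rule on mean fWA: predict long-term sinus-rhythm
# maintenance (SUCCESS) when baseline meanfWA is at least the amplitude
# cutoff OR the relative decrease in meanfWA across the procedure is at most
# the decrease cutoff; otherwise predict FAILURE. Both comparisons are
# inclusive, and an amplitude increase (negative decrease) always lands in
# the SUCCESS branch.

#' Construct a decision rule
#' @param baseline_cutoff baseline meanfWA threshold in mV (study value
#'   0.044).
#' @param decrease_cutoff relative-decrease threshold in percent (study value
#'   11).
#' @return list of class `decision_rule`.
#' @export
decision_rule <- function(baseline_cutoff = 0.044, decrease_cutoff = 11) {
  stopifnot(baseline_cutoff > 0, is.finite(decrease_cutoff))
  structure(list(baseline_cutoff = baseline_cutoff,
                 decrease_cutoff = decrease_cutoff),
            class = "decision_rule")
}

#' Classify a patient with the two-threshold rule
#' @param rule a [decision_rule()].
#' @param baseline_meanfwa baseline meanfWA, mV (> 0).
#' @param decrease_pct relative decrease of meanfWA in percent (positive =
#'   amplitude fell; negative values, i.e. increases, predict SUCCESS).
#' @return character vector of `"SUCCESS"` / `"FAILURE"` (vectorized).
#' @export
classify <- function(rule, baseline_meanfwa, decrease_pct) {
  stopifnot(inherits(rule, "decision_rule"))
  if (any(baseline_meanfwa <= 0)) stop("baseline meanfWA must be positive")
  ifelse(baseline_meanfwa >= rule$baseline_cutoff |
           decrease_pct <= rule$decrease_cutoff, "SUCCESS", "FAILURE")
}

cohort_decrease_pct <- function(cohort) {
  if ("decrease_pct" %in% names(cohort)) return(cohort$decrease_pct)
  100 * (cohort$meanfwa_baseline - cohort$meanfwa_endwpvi) /
    cohort$meanfwa_baseline
}

#' Evaluate a decision rule on a cohort
#'
#' SUCCESS is the positive class. Metrics come from the confusion table of
#' predicted vs actual outcome over SUCCESS/FAILURE rows (other labels are
#' dropped).
#'
#' @param rule a [decision_rule()].
#' @param cohort a `cohort_table` with `meanfwa_baseline` and either
#'   `decrease_pct` or `meanfwa_endwpvi`.
#' @return list with `sensitivity`, `specificity`, `ppv`, `npv`, `confusion`
#'   (2x2 integer matrix, predicted x actual) and `predictions`.
#' @export
evaluate_rule <- function(rule, cohort) {
  keep <- cohort$outcome %in% c("SUCCESS", "FAILURE")
  co <- cohort[keep, , drop = FALSE]
  pred <- classify(rule, co$meanfwa_baseline, cohort_decrease_pct(co))
  actual <- co$outcome
  tp <- sum(pred == "SUCCESS" & actual == "SUCCESS")
  fp <- sum(pred == "SUCCESS" & actual == "FAILURE")
  fn <- sum(pred == "FAILURE" & actual == "SUCCESS")
  tn <- sum(pred == "FAILURE" & actual == "FAILURE")
  conf <- matrix(as.integer(c(tp, fn, fp, tn)), 2L, 2L,
                 dimnames = list(predicted = c("SUCCESS", "FAILURE"),
                                 actual = c("SUCCESS", "FAILURE")))
  div <- function(a, b) if (b > 0) a / b else NA_real_
  list(sensitivity = div(tp, tp + fn), specificity = div(tn, tn + fp),
       ppv = div(tp, tp + fp), npv = div(tn, tn + fn),
       confusion = conf,
       predictions = data.frame(patient_id = co$patient_id, predicted = pred,
                                actual = actual, stringsAsFactors = FALSE))
}

#' Fit the two thresholds from a cohort
#'
#' Two-stage procedure mirroring the rule's structure: (1) the baseline
#' cutoff is the sensitivity+specificity-optimal ROC threshold of baseline
#' meanfWA for SUCCESS; (2) among patients below that cutoff, the decrease
#' cutoff is the optimal ROC threshold of the relative decrease (small
#' decrease predicts SUCCESS). If the second stage sees a single class it
#' falls back to the marginal ROC cutoff over the whole cohort, with a
#' warning.
#'
#' @param cohort a `cohort_table` with both outcome classes.
#' @return list with `rule` (the fitted [decision_rule()]), `metrics`
#'   (evaluation on the fitting cohort) and the two stage `roc` objects.
#' @export
fit_rule <- function(cohort) {
  keep <- cohort$outcome %in% c("SUCCESS", "FAILURE")
  co <- cohort[keep, , drop = FALSE]
  y <- co$outcome == "SUCCESS"
  if (!any(y) || all(y)) stop("both outcome classes are required")
  roc1 <- roc_analysis(co$meanfwa_baseline, y, direction = "gte")
  below <- co$meanfwa_baseline < roc1$cutoff
  dec <- cohort_decrease_pct(co)
  y2 <- y[below]
  if (length(unique(y2)) < 2L) {
    warning("single class below the baseline cutoff; ",
            "using the marginal decrease cutoff")
    roc2 <- roc_analysis(dec, y, direction = "lte")
  } else {
    roc2 <- roc_analysis(dec[below], y2, direction = "lte")
  }
  rule <- decision_rule(baseline_cutoff = roc1$cutoff,
                        decrease_cutoff = roc2$cutoff)
  # keep the decrease branch only if it improves SE+SP over the
  # baseline-threshold-only rule; otherwise make it inert (a cutoff below
  # every observed decrease), so the fitted rule never underperforms the
  # single-threshold rule it extends
  inert <- decision_rule(baseline_cutoff = roc1$cutoff,
                         decrease_cutoff = min(dec) - 1)
  m_rule <- evaluate_rule(rule, co)
  m_inert <- evaluate_rule(inert, co)
  j <- function(m) m$sensitivity + m$specificity
  if (!isTRUE(j(m_rule) > j(m_inert))) {
    rule <- inert
    m_rule <- m_inert
  }
  list(rule = rule, metrics = m_rule,
       roc_baseline = roc1, roc_decrease = roc2)
}

#' @export
print.decision_rule <- function(x, ...) {
  cat(sprintf("<decision_rule> predict SUCCESS if baseline meanfWA >= %g mV OR decrease <= %g%%\n",
              x$baseline_cutoff, x$decrease_cutoff))
  invisible(x)
}
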