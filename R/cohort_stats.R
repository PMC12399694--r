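# Cohort-level summaries in the two shapes ablation studies report:
# per-lead group comparisons (median/IQR + Mann-Whitney p) and per-predictor
# performance (logistic odds ratio + ROC with optimal cutoff and SE/SP/PPV/
# NPV). SUCCESS is the positive class throughout.

#' Per-lead group comparison between SUCCESS and FAILURE
#'
#' @param cohort a `cohort_table`.
#' @param epoch `"baseline"` or `"endwpvi"`.
#' @return data.frame: one row per lead (plus `meanfwa`), group medians and
#'   quartiles (mV) and the Mann-Whitney two-sided p.
#' @export
compare_groups <- function(cohort, epoch = c("baseline", "endwpvi")) {
  epoch <- match.arg(epoch)
  co <- cohort[cohort$outcome %in% c("SUCCESS", "FAILURE"), , drop = FALSE]
  cols <- c(cohort_lead_columns(co, epoch), paste0("meanfwa_", epoch))
  rows <- lapply(cols, function(cl) {
    s <- co[[cl]][co$outcome == "SUCCESS"]
    f <- co[[cl]][co$outcome == "FAILURE"]
    qs <- stats::quantile(s, c(0.5, 0.25, 0.75), names = FALSE)
    qf <- stats::quantile(f, c(0.5, 0.25, 0.75), names = FALSE)
    data.frame(variable = sub(paste0("_", epoch, "$"), "", sub("^fwa_", "", cl)),
               success_median = qs[1L], success_q25 = qs[2L], success_q75 = qs[3L],
               failure_median = qf[1L], failure_q25 = qf[2L], failure_q75 = qf[3L],
               p_value = mann_whitney(s, f)$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-predictor outcome analysis (odds ratio + ROC)
#'
#' For each per-lead fWA column at the chosen epoch (plus meanfWA), fits a
#' univariate logistic model for SUCCESS and runs the ROC analysis with the
#' sensitivity+specificity-optimal cutoff. Amplitude predictors report the
#' odds ratio per 0.01 mV; relative-change predictors per 1 percentage point.
#'
#' @param cohort a `cohort_table`.
#' @param epoch `"baseline"`, `"endwpvi"`, or `"change"` (per-lead relative
#'   change in percent, computed from the two epochs).
#' @param or_increment override the OR increment.
#' @return data.frame with OR (CI, p), AUC (CI), cutoff, SE/SP/PPV/NPV per
#'   predictor.
#' @export
predictor_analysis <- function(cohort, epoch = c("baseline", "endwpvi", "change"),
                               or_increment = NULL) {
  epoch <- match.arg(epoch)
  co <- cohort[cohort$outcome %in% c("SUCCESS", "FAILURE"), , drop = FALSE]
  y <- co$outcome == "SUCCESS"
  if (epoch == "change") {
    base_cols <- cohort_lead_columns(co, "baseline")
    leads <- sub("^fwa_", "", sub("_baseline$", "", base_cols))
    vals <- lapply(leads, function(l)
      100 * (co[[paste0("fwa_", l, "_endwpvi")]] -
               co[[paste0("fwa_", l, "_baseline")]]) /
        co[[paste0("fwa_", l, "_baseline")]])
    names(vals) <- paste0("delta_", leads, "_pct")
    inc <- or_increment %||% 1
  } else {
    cols <- c(cohort_lead_columns(co, epoch), paste0("meanfwa_", epoch))
    vals <- lapply(cols, function(cl) co[[cl]])
    names(vals) <- sub(paste0("_", epoch, "$"), "", sub("^fwa_", "", cols))
    inc <- or_increment %||% 0.01
  }
  rows <- lapply(names(vals), function(nm) {
    fit <- logistic_fit_univariate(vals[[nm]], y, increment = inc)
    roc <- roc_analysis(vals[[nm]], y)
    data.frame(predictor = nm, or = fit$odds_ratio,
               or_lower = fit$or_ci[1L], or_upper = fit$or_ci[2L],
               or_p = fit$p_value, or_increment = inc,
               auc = roc$auc, auc_lower = roc$auc_ci[1L],
               auc_upper = roc$auc_ci[2L],
               cutoff = roc$cutoff, direction = roc$direction,
               sensitivity = roc$sensitivity, specificity = roc$specificity,
               ppv = roc$ppv, npv = roc$npv,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
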