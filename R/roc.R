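#' ROC analysis with a sensitivity+specificity-optimal cutoff
#'
#' AUC over all empirical thresholds (trapezoidal; equal by construction to
#' the normalized Mann-Whitney U statistic). The optimal cutoff maximizes
#' SE + SP; among ties the cutoff with higher sensitivity wins, then the
#' smaller threshold. Direction is chosen automatically so that AUC >= 0.5
#' ("gte": score >= cutoff predicts positive; "lte": score <= cutoff does).
#' The AUC confidence interval is DeLong's.
#'
#' @param scores numeric predictor.
#' @param labels logical or 0/1; `TRUE`/1 is the positive class.
#' @param direction `"auto"`, `"gte"` or `"lte"`.
#' @param conf_level CI level for the AUC (default 0.95).
#' @return list of class `roc_result`: `auc`, `auc_ci`, `cutoff`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `direction`, and the full
#'   `thresholds` table.
#' @export
roc_analysis <- function(scores, labels, direction = c("auto", "gte", "lte"),
                         conf_level = 0.95) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  if (!any(labels) || all(labels)) stop("both classes must be present")
  pos <- scores[labels]; neg <- scores[!labels]
  auc_gte <- auc_mw(pos, neg)
  if (direction == "auto") direction <- if (auc_gte >= 0.5) "gte" else "lte"
  s <- if (direction == "gte") scores else -scores
  p <- if (direction == "gte") pos else -pos
  ng <- if (direction == "gte") neg else -neg
  auc <- auc_mw(p, ng)

  thr <- sort(unique(s))
  # candidate cutoffs: each observed value (>= thr predicts positive), plus
  # one above the maximum (predict-none)
  cand <- c(thr, max(thr) + 1)
  se <- vapply(cand, function(cth) mean(p >= cth), numeric(1))
  sp <- vapply(cand, function(cth) mean(ng < cth), numeric(1))
  j <- se + sp
  best <- which(j >= max(j) - 1e-12)
  if (length(best) > 1L) best <- best[order(-se[best], cand[best])][1L]
  cth <- cand[best]
  tp <- sum(p >= cth); fn <- sum(p < cth)
  fp <- sum(ng >= cth); tn <- sum(ng < cth)
  ci <- delong_ci(p, ng, auc, conf_level)
  structure(list(
    auc = auc, auc_ci = ci,
    cutoff = if (direction == "gte") cth else -cth,
    sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    direction = direction,
    thresholds = data.frame(
      cutoff = if (direction == "gte") cand else -cand,
      sensitivity = se, specificity = sp)),
    class = "roc_result")
}

# AUC as the normalized U statistic (ties count 1/2)
auc_mw <- function(pos, neg) {
  r <- rank(c(pos, neg))
  n1 <- length(pos); n0 <- length(neg)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong variance of the AUC from placement values
delong_ci <- function(pos, neg, auc, conf_level) {
  n1 <- length(pos); n0 <- length(neg)
  v10 <- vapply(pos, function(p) mean((p > neg) + 0.5 * (p == neg)), numeric(1))
  v01 <- vapply(neg, function(q) mean((pos > q) + 0.5 * (pos == q)), numeric(1))
  s2 <- stats::var(v10) / n1 + stats::var(v01) / n0
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  lo <- max(0, auc - z * sqrt(s2)); hi <- min(1, auc + z * sqrt(s2))
  c(lower = lo, upper = hi)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (%.3f, %.3f); cutoff %s %g: SE %.2f SP %.2f PPV %.2f NPV %.2f\n",
              x$auc, x$auc_ci[1L], x$auc_ci[2L],
              if (x$direction == "gte") ">=" else "<=", x$cutoff,
              x$sensitivity, x$specificity, x$ppv, x$npv))
  invisible(x)
}
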