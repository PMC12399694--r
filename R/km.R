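#' Kaplan-Meier product-limit estimate
#'
#' @param times nonnegative follow-up times.
#' @param events 0 (censored) / 1 (event).
#' @return list of class `km_curve`: `time` (distinct event times), `n_risk`,
#'   `n_event`, `survival`, plus `censor_times`.
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) == length(events), all(times >= 0),
            all(events %in% c(0, 1)))
  if (!length(times)) stop("empty group")
  ut <- sort(unique(times[events == 1]))
  n_risk <- vapply(ut, function(t) sum(times >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(times == t & events == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(list(time = ut, n_risk = n_risk, n_event = n_event,
                 survival = surv,
                 censor_times = sort(times[events == 0])),
            class = "km_curve")
}

#' Survival probability at given times
#' @param km a `km_curve`.
#' @param t times at which to evaluate (step function, right-continuous).
#' @export
km_survival_at <- function(km, t) {
  vapply(t, function(tt) {
    i <- sum(km$time <= tt)
    if (i == 0L) 1 else km$survival[i]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected log-rank with hypergeometric variance,
#' chi-squared with 1 df.
#'
#' @param times,events follow-up times and event flags.
#' @param group two-level grouping vector.
#' @return list with `statistic`, `p_value`, `observed`, `expected` (per
#'   group).
#' @export
logrank_test <- function(times, events, group) {
  g <- droplevels(as.factor(group))
  stopifnot(length(times) == length(events), length(times) == length(g))
  if (nlevels(g) != 2L)
    stop("log-rank comparison requires exactly two groups")
  ut <- sort(unique(times[events == 1]))
  o1 <- e1 <- v <- 0
  for (t in ut) {
    at <- times >= t
    n <- sum(at); n1 <- sum(at & g == levels(g)[1L])
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g == levels(g)[1L])
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- if (v > 0) (o1 - e1)^2 / v else 0
  obs <- c(o1, sum(events) - o1)
  expd <- c(e1, sum(events) - e1)
  names(obs) <- names(expd) <- levels(g)
  list(statistic = stat,
       p_value = if (v > 0) stats::pchisq(stat, 1, lower.tail = FALSE) else 1,
       observed = obs, expected = expd)
}
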