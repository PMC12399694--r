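#' Univariate logistic regression with odds ratio per increment
#'
#' Newton-Raphson maximum likelihood for intercept + slope, Wald 95% CI.
#' The odds ratio is reported per `increment` of the predictor (defaults that
#' make clinical sense for this pipeline: 0.01 mV for amplitude predictors,
#' 1 percentage point for relative-change predictors).
#'
#' @param x numeric predictor.
#' @param labels logical or 0/1 outcome; `TRUE`/1 is the positive class.
#' @param increment predictor units per OR step.
#' @param conf_level Wald CI level.
#' @param max_iter,tol Newton-Raphson controls.
#' @return list of class `logistic_fit`: `coef` (intercept, slope per raw
#'   unit), `se`, `odds_ratio`, `or_ci`, `p_value` (Wald, slope), `increment`,
#'   `separation` flag.
#' @export
logistic_fit_univariate <- function(x, labels, increment = 1,
                                    conf_level = 0.95,
                                    max_iter = 50L, tol = 1e-10) {
  y <- as.numeric(as.logical(labels))
  stopifnot(length(x) == length(y), all(is.finite(x)))
  if (!any(y == 1) || !any(y == 0)) stop("both classes must be present")
  if (stats::sd(x) == 0) {
    warning("constant predictor: slope not identifiable")
    return(structure(list(coef = c(stats::qlogis(mean(y)), NA_real_),
                          se = c(NA_real_, NA_real_),
                          odds_ratio = NA_real_, or_ci = c(NA_real_, NA_real_),
                          p_value = NA_real_, increment = increment,
                          separation = TRUE),
                     class = "logistic_fit"))
  }
  # standardize internally for a well-conditioned Hessian
  mx <- mean(x); sx <- stats::sd(x)
  z <- (x - mx) / sx
  X <- cbind(1, z)
  beta <- c(stats::qlogis(mean(y)), 0)
  separation <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    wt <- mu * (1 - mu)
    grad <- crossprod(X, y - mu)
    H <- crossprod(X, X * wt)
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) { separation <- TRUE; break }
    beta <- unname(beta + drop(step))
    if (max(abs(step)) < tol) break
    if (abs(beta[2L]) > 30) { separation <- TRUE; break }
  }
  eta <- drop(X %*% beta); mu <- stats::plogis(eta)
  H <- crossprod(X, X * (mu * (1 - mu)))
  cov <- tryCatch(solve(H), error = function(e) matrix(NA_real_, 2, 2))
  # back-transform to raw predictor units
  beta <- unname(beta)
  slope <- beta[2L] / sx
  intercept <- beta[1L] - beta[2L] * mx / sx
  se_slope <- sqrt(cov[2L, 2L]) / sx
  if (separation) {
    warning("(quasi-)separation detected: odds ratio is not finite")
    return(structure(list(coef = c(intercept, slope),
                          se = c(NA_real_, NA_real_),
                          odds_ratio = if (slope > 0) Inf else 0,
                          or_ci = c(NA_real_, NA_real_), p_value = NA_real_,
                          increment = increment, separation = TRUE),
                     class = "logistic_fit"))
  }
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  or <- exp(slope * increment)
  ci <- exp((slope + c(-1, 1) * zq * se_slope) * increment)
  pw <- 2 * stats::pnorm(-abs(slope / se_slope))
  structure(list(coef = c(intercept = intercept, slope = slope),
                 se = c(NA_real_, slope = se_slope),
                 odds_ratio = or, or_ci = c(lower = ci[1L], upper = ci[2L]),
                 p_value = pw, increment = increment, separation = FALSE),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> OR %.3f (%.3f, %.3f) per %g unit(s); p = %.4g%s\n",
              x$odds_ratio, x$or_ci[1L], x$or_ci[2L], x$increment,
              x$p_value, if (x$separation) " [separation]" else ""))
  invisible(x)
}
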