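# Rank and contingency tests implemented from first principles (the pipeline
# treats these as part of its own contract; base-R equivalents are used only
# as cross-checks in the test suite).

#' Mann-Whitney U test
#'
#' U with midrank ties. Two-sided p is exact (complete enumeration of rank
#' assignments) when n + m <= 16 and there are no ties, otherwise a normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y numeric samples.
#' @return list with `U` (statistic for `x`), `p_value`, `method`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  if (n1 + n2 <= 16 && !ties) {
    # exact: null distribution of U over all C(n1+n2, n1) assignments
    dist <- u_exact_distribution(n1, n2)
    mu <- n1 * n2 / 2
    p <- sum(dist$prob[abs(dist$u - mu) >= abs(U - mu) - 1e-9])
    list(U = U, p_value = min(1, p), method = "exact")
  } else {
    mu <- n1 * n2 / 2
    nt <- n1 + n2
    tie_tab <- table(c(x, y))
    tiecorr <- sum(tie_tab^3 - tie_tab) / (nt * (nt - 1))
    sigma2 <- n1 * n2 / 12 * (nt + 1 - tiecorr)
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    list(U = U, p_value = min(1, 2 * stats::pnorm(-abs(z))),
         method = "normal approximation")
  }
}

# exact null distribution of U for sample sizes n1, n2 (no ties), by the
# standard two-sample recursion on arrangement counts:
#   N(i, j, u) = N(i-1, j, u-j) + N(i, j-1, u)
# (the largest pooled observation is either from sample 1, contributing j
# pairwise wins, or from sample 2)
u_exact_distribution <- function(n1, n2) {
  cnt <- vector("list", n2 + 1L)
  for (j in 0:n2) cnt[[j + 1L]] <- 1  # i = 0 row: only u = 0
  for (i in seq_len(n1)) {
    prev <- cnt
    cnt[[1L]] <- 1  # j = 0: only u = 0
    for (j in seq_len(n2)) {
      a <- c(rep(0, j), prev[[j + 1L]])          # N(i-1, j, u-j)
      b <- cnt[[j]]                              # N(i, j-1, u)
      len <- i * j + 1L
      length(a) <- len; length(b) <- len
      a[is.na(a)] <- 0; b[is.na(b)] <- 0
      cnt[[j + 1L]] <- a + b
    }
  }
  counts <- cnt[[n2 + 1L]]
  data.frame(u = 0:(n1 * n2), prob = counts / choose(n1 + n2, n1))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p by summing all hypergeometric table probabilities not larger
#' than the observed one. A zero margin yields p = 1 with a warning.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return list with `p_value`, `odds_ratio` (sample ad/bc).
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2L), all(tab >= 0), all(tab == round(tab)))
  r1 <- sum(tab[1L, ]); c1 <- sum(tab[, 1L]); n <- sum(tab)
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) {
    warning("zero margin: Fisher p = 1")
    return(list(p_value = 1,
                odds_ratio = unname(tab[1, 1] * tab[2, 2] /
                                      max(1, tab[1, 2] * tab[2, 1]))))
  }
  support <- max(0L, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1L, 1L], c1, n - c1, r1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(p_value = min(1, p),
       odds_ratio = unname((tab[1, 1] * tab[2, 2]) /
                             (tab[1, 2] * tab[2, 1])))
}

#' Pearson chi-squared test for a 2x2 table
#'
#' 1 df, no continuity correction by default.
#' @param tab 2x2 count matrix.
#' @param correct apply the Yates continuity correction.
#' @return list with `statistic`, `p_value`, `df`.
#' @export
chi2_test <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2L), all(tab >= 0))
  n <- sum(tab)
  exp <- outer(rowSums(tab), colSums(tab)) / n
  if (any(exp == 0)) stop("zero margin: chi-squared undefined")
  d <- abs(tab - exp)
  if (correct) d <- pmax(0, d - 0.5)
  stat <- sum(d^2 / exp)
  list(statistic = stat, p_value = stats::pchisq(stat, 1, lower.tail = FALSE),
       df = 1L)
}
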