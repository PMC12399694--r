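test_that("Mann-Whitney exact p matches complete enumeration", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 0.1)   # 2 of the C(6,3)=20 arrangements are as extreme
  expect_equal(r$method, "exact")

  # brute-force enumeration oracle for a non-degenerate case
  x <- c(1.2, 3.4, 5.1); y <- c(2.2, 2.9, 6.3, 7.0)
  r2 <- mann_whitney(x, y)
  pool <- c(x, y)
  combs <- utils::combn(7, 3)
  us <- apply(combs, 2, function(ix) {
    rk <- rank(pool)
    sum(rk[ix]) - 6
  })
  mu <- 3 * 4 / 2
  p_oracle <- mean(abs(us - mu) >= abs(r2$U - mu) - 1e-9)
  expect_equal(r2$p_value, p_oracle)
})

test_that("Mann-Whitney is symmetric and agrees with wilcox.test", {
  xx <- c(5, 1, 9, 3)
  expect_equal(mann_whitney(xx, xx)$p_value, 1)

  set.seed(7)
  x <- rnorm(500); y <- rnorm(500, 0.15)
  r <- mann_whitney(x, y)
  ref <- stats::wilcox.test(x, y, correct = TRUE, exact = FALSE)
  expect_equal(r$U, unname(ref$statistic))
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-6)

  # tied data against the tie-corrected reference
  set.seed(8)
  xt <- sample(1:5, 60, TRUE); yt <- sample(2:6, 50, TRUE)
  rt <- mann_whitney(xt, yt)
  reft <- suppressWarnings(stats::wilcox.test(xt, yt, correct = TRUE,
                                              exact = FALSE))
  expect_equal(rt$p_value, reft$p.value, tolerance = 1e-6)
})

test_that("Fisher exact p equals hypergeometric enumeration on small tables", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  # observed association in the direction of the antiarrhythmic-use contrast
  r <- fisher_exact_2x2(matrix(c(0, 11, 54, 15), 2))
  expect_lt(r$p_value, 0.001)

  set.seed(3)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    cells <- as.vector(stats::rmultinom(1, n, prob = runif(4, 0.1, 1)))
    tab <- matrix(cells, 2)
    got <- suppressWarnings(fisher_exact_2x2(tab)$p_value)
    ref <- stats::fisher.test(tab)$p.value
    expect_equal(got, ref, tolerance = 1e-9)
  }
})

test_that("chi-squared matches the base implementation", {
  tab <- matrix(c(20, 10, 15, 25), 2)
  r <- chi2_test(tab)
  ref <- stats::chisq.test(tab, correct = FALSE)
  expect_equal(r$statistic, unname(ref$statistic))
  expect_equal(r$p_value, ref$p.value)
  ry <- chi2_test(tab, correct = TRUE)
  refy <- stats::chisq.test(tab, correct = TRUE)
  expect_equal(ry$statistic, unname(refy$statistic))
})

test_that("ROC analysis: separation, U identity, exhaustive-search cutoff", {
  r <- roc_analysis(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$auc, 1)
  expect_equal(r$cutoff, 3)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)

  set.seed(5)
  for (i in 1:40) {
    n1 <- sample(5:25, 1); n0 <- sample(5:25, 1)
    sc <- c(rnorm(n1, 0.5), rnorm(n0))
    lb <- rep(c(1, 0), c(n1, n0))
    r <- roc_analysis(sc, lb, direction = "gte")
    # AUC equals the normalized Mann-Whitney statistic
    u <- mann_whitney(sc[lb == 1], sc[lb == 0])$U
    expect_equal(r$auc, u / (n1 * n0), tolerance = 1e-12)
    # optimal cutoff by exhaustive search over all candidate thresholds
    cand <- c(sort(unique(sc)), max(sc) + 1)
    j <- vapply(cand, function(cth)
      mean(sc[lb == 1] >= cth) + mean(sc[lb == 0] < cth), numeric(1))
    expect_equal(r$sensitivity + r$specificity, max(j), tolerance = 1e-12)
  }
})

test_that("ROC direction auto-flips so that low scores can predict success", {
  set.seed(2)
  sc <- c(rnorm(30, 0), rnorm(30, 1))
  lb <- rep(c(1, 0), each = 30)   # positives have LOWER scores
  r <- roc_analysis(sc, lb)
  expect_identical(r$direction, "lte")
  expect_gte(r$auc, 0.5)
  expect_error(roc_analysis(sc, rep(1, 60)), "both classes")
})

test_that("ROC AUC and CI agree with pROC on a representative sample", {
  skip_if_not_installed("pROC")
  set.seed(9)
  sc <- c(rnorm(54, 0.6), rnorm(26))
  lb <- rep(c(1, 0), c(54, 26))
  r <- roc_analysis(sc, lb, direction = "gte")
  ref <- pROC::roc(lb, sc, direction = "<", quiet = TRUE)
  expect_equal(r$auc, as.numeric(ref$auc), tolerance = 1e-12)
  ci <- pROC::ci.auc(ref, method = "delong")
  expect_equal(unname(r$auc_ci), c(ci[1], ci[3]), tolerance = 1e-6)
})

test_that("logistic OR reduces to the 2x2 cross-product ratio", {
  a <- 12; b <- 8; c_ <- 5; d <- 15
  x <- rep(c(1, 1, 0, 0), c(a, b, c_, d))
  y <- rep(c(1, 0, 1, 0), c(a, b, c_, d))
  fit <- logistic_fit_univariate(x, y, increment = 1)
  expect_equal(fit$odds_ratio, (a * d) / (b * c_), tolerance = 1e-6)
})

test_that("logistic fit agrees with glm and flags degenerate inputs", {
  set.seed(4)
  x <- rnorm(120); y <- rbinom(120, 1, plogis(-0.3 + 0.8 * x))
  fit <- logistic_fit_univariate(x, y, increment = 1)
  ref <- stats::glm(y ~ x, family = binomial())
  expect_equal(unname(fit$coef["slope"]), unname(coef(ref)["x"]),
               tolerance = 1e-6)
  expect_equal(unname(fit$se["slope"]),
               unname(summary(ref)$coefficients["x", "Std. Error"]),
               tolerance = 1e-5)

  expect_warning(fc <- logistic_fit_univariate(rep(1, 20), rep(c(0, 1), 10)),
                 "constant")
  expect_true(fc$separation)
  xs <- c(rep(0, 10), rep(1, 10)); ys <- xs
  expect_warning(fs <- logistic_fit_univariate(xs, ys), "separation")
  expect_true(fs$separation)
})

test_that("Kaplan-Meier matches the hand-computed product limit", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$n_risk, c(3, 2, 1))

  kc <- km_estimate(c(4, 6, 9), c(0, 0, 0))
  expect_length(kc$time, 0)
  expect_equal(km_survival_at(kc, c(0, 5, 10)), c(1, 1, 1))
})

test_that("Kaplan-Meier and log-rank agree with the survival package", {
  skip_if_not_installed("survival")
  set.seed(12)
  time <- round(rexp(60, 1 / 20), 1)
  ev <- rbinom(60, 1, 0.7)
  grp <- rep(c("A", "B"), 30)
  km <- km_estimate(time[grp == "A"], ev[grp == "A"])
  ref <- survival::survfit(survival::Surv(time, ev) ~ 1,
                           subset = grp == "A")
  rs <- summary(ref, times = km$time)
  expect_equal(km$survival, rs$surv, tolerance = 1e-12)

  lr <- logrank_test(time, ev, grp)
  refd <- survival::survdiff(survival::Surv(time, ev) ~ grp)
  expect_equal(lr$statistic, refd$chisq, tolerance = 1e-9)
  expect_equal(unname(lr$observed), unname(refd$obs))
  expect_equal(unname(lr$expected), unname(refd$exp), tolerance = 1e-9)
})

test_that("log-rank on identical groups is null", {
  time <- c(1, 2, 3, 4, 1, 2, 3, 4)
  ev <- rep(1, 8)
  grp <- rep(c("A", "B"), each = 4)
  lr <- logrank_test(time, ev, grp)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)
  expect_error(logrank_test(1:3, c(1, 1, 1), rep("A", 3)), "two|group")
})

test_that("group comparison and predictor tables have the reported shape", {
  co <- simulate_cohort(cohort_sim_params(n_success = 30, n_failure = 15,
                                          seed = 2))
  cmp <- compare_groups(co, "endwpvi")
  expect_equal(nrow(cmp), 13L)  # 12 leads + meanfwa
  expect_true(all(c("success_median", "failure_median", "p_value") %in%
                    names(cmp)))
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))

  pa <- predictor_analysis(co, "endwpvi")
  expect_equal(nrow(pa), 13L)
  expect_equal(unique(pa$or_increment), 0.01)
  pc <- predictor_analysis(co, "change")
  expect_equal(unique(pc$or_increment), 1)
  expect_true(all(pa$auc >= 0.5))
})
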