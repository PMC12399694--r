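test_that("sliding extrema find every crest of a slow oscillation", {
  rec <- sine_record(a = 0.03, f = 6, duration_s = 1)
  ext <- detect_extrema(rec)$V1
  # 6 Hz over 1 s: every interior crest kept, each at +a within 1%
  expect_gte(nrow(ext$maxima), 5)
  expect_lte(nrow(ext$maxima), 7)
  expect_true(all(abs(ext$maxima$value - 0.03) < 0.0003))
  expect_true(all(abs(ext$minima$value + 0.03) < 0.0003))
})

test_that("stepped extrema produce one max and min per 100-ms window", {
  rec <- sine_record(a = 0.03, f = 6, duration_s = 60)
  ext <- detect_extrema(rec, mode = "stepped")$V1
  expect_equal(nrow(ext$maxima), 600L)
  expect_equal(nrow(ext$minima), 600L)

  const <- ecg_record(cbind(V1 = rep(0.7, 2000)), fs = 2000)
  ec <- detect_extrema(const, mode = "stepped")$V1
  expect_true(all(ec$maxima$value == 0.7))
  expect_true(all(ec$minima$value == 0.7))
})

test_that("signals shorter than one window are rejected", {
  rec <- ecg_record(cbind(V1 = rnorm(100)), fs = 2000)
  expect_error(detect_extrema(rec), "shorter than one")
})

test_that("envelopes of a pure sinusoid sit at +/- its amplitude", {
  rec <- sine_record(a = 0.025, f = 6, duration_s = 10)
  ext <- detect_extrema(rec)$V1
  env <- estimate_envelopes(ext, fs = 2000, n_samples = 20000)
  mid <- 2000:18000
  expect_true(all(abs(env$upper[mid] / 0.025 - 1) < 0.05))
  expect_true(all(abs(env$lower[mid] / -0.025 - 1) < 0.05))
})

test_that("envelopes track slow amplitude modulation", {
  fs <- 2000; t <- (seq_len(10 * fs) - 1) / fs
  a <- 0.03 * (1 + 0.5 * sin(2 * pi * 0.2 * t))
  rec <- ecg_record(cbind(V1 = a * sin(2 * pi * 6 * t)), fs = fs)
  ext <- detect_extrema(rec)$V1
  env <- estimate_envelopes(ext, fs, length(t))
  mid <- 2000:18000
  expect_true(all(abs(env$upper[mid] / a[mid] - 1) < 0.10))
})

test_that("too few extrema raise an informative error", {
  ext <- list(maxima = data.frame(index = c(1, 50), value = c(1, 1)),
              minima = data.frame(index = c(25, 75), value = c(-1, -1)))
  expect_error(estimate_envelopes(ext, 2000, 100), "too few extrema")
})

test_that("fWA is the mean envelope separation, floored at zero", {
  env <- list(upper = rep(0.02, 100), lower = rep(-0.02, 100))
  expect_equal(compute_fwa(env), 0.04)
  env2 <- list(upper = rep(0.01, 100), lower = rep(0.01, 100))
  expect_equal(compute_fwa(env2), 0)
  env3 <- list(upper = rep(-0.01, 100), lower = rep(0.01, 100))
  expect_message(v <- compute_fwa(env3), "floored")
  expect_equal(v, 0)
})

test_that("full chain recovers twice the sinusoid amplitude", {
  rec <- sine_record(a = 0.025, f = 6, duration_s = 10)
  m <- measure_fwa(rec, trim = 0.1)
  expect_equal(unname(m$per_lead_fwa["V1"]), 0.050, tolerance = 0.003 / 0.05)
})

test_that("meanfwa aggregates leads and flags missing ones", {
  m <- structure(list(per_lead_fwa = c(I = 0.02, II = 0.06, V1 = 0.04),
                      meanfwa = 0.04), class = "fwa_measurement")
  expect_equal(mean_fwa(m), 0.04)
  expect_equal(mean_fwa(m, c("I", "II")), 0.04)
  expect_error(mean_fwa(m, c("I", "V9")), "V9")
  # brute-force oracle on random per-lead values
  set.seed(1)
  v <- runif(12, 0.01, 0.08); names(v) <- ECG_LEADS_12
  m2 <- structure(list(per_lead_fwa = v, meanfwa = NA), class = "fwa_measurement")
  expect_equal(mean_fwa(m2), sum(v) / 12)
})

test_that("relative change and decrease follow the sign convention", {
  mk <- function(v, ep) structure(
    list(per_lead_fwa = c(V1 = v), meanfwa = v, epoch = ep),
    class = "fwa_measurement")
  ch <- relative_change(mk(0.040, "baseline"), mk(0.036, "endWPVI"))
  expect_equal(ch$meanfwa_delta_pct, -10)
  expect_equal(ch$decrease_pct, 10)
  expect_equal(unname(ch$per_lead_delta_pct["V1"]), -10)

  expect_equal(relative_change(mk(0.04, "baseline"),
                               mk(0.04, "endWPVI"))$meanfwa_delta_pct, 0)
  ch3 <- relative_change(mk(0.044, "baseline"), mk(0.0506, "endWPVI"))
  expect_equal(ch3$meanfwa_delta_pct, 15, tolerance = 1e-9)
  expect_error(relative_change(mk(0, "baseline"), mk(0.01, "endWPVI")),
               "baseline")
})

test_that("fWA is scale-equivariant and monotone in generated amplitude", {
  sim <- clean_atrial(duration_s = 8, amp = c(V1 = 0.04))
  m1 <- measure_fwa(sim$record, trim = 0.1)$per_lead_fwa
  rec3 <- ecg_record(sim$record$signals * 3, fs = 2000, lead_labels = "V1")
  m3 <- measure_fwa(rec3, trim = 0.1)$per_lead_fwa
  expect_equal(unname(m3 / m1), 3, tolerance = 1e-7)

  amps <- c(0.01, 0.03, 0.05, 0.08, 0.10)
  got <- vapply(amps, function(a) {
    v <- vapply(1:3, function(s)
      measure_fwa(clean_atrial(duration_s = 6, amp = c(V1 = a),
                               seed = s)$record,
                  trim = 0.1)$per_lead_fwa, numeric(1))
    mean(v)
  }, numeric(1))
  expect_true(all(diff(got) > 0))
})

test_that("meanfwa of identical leads equals the per-lead value exactly", {
  rec <- sine_record(a = 0.02, f = 6, duration_s = 5,
                     leads = c("I", "II", "III"))
  m <- measure_fwa(rec, trim = 0.1)
  expect_equal(m$meanfwa, unname(m$per_lead_fwa["I"]))
})
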