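test_that("atrial-only record carries the requested peak-to-trough amplitude", {
  sim <- clean_atrial(duration_s = 5, amp = c(V1 = 0.05))
  expect_equal(sim$record$signals, sim$atrial, ignore_attr = TRUE)
  # per-cycle max - min equals the requested amplitude within 2%
  x <- sim$atrial[, 1]
  fs <- 2000; f <- sim$params$f_wave_freq
  cyc <- floor((seq_along(x) - 1) / (fs / f))
  pt <- tapply(x, cyc, function(v) max(v) - min(v))
  pt <- pt[2:(length(pt) - 1)]  # complete cycles only
  expect_true(all(abs(pt / 0.05 - 1) < 0.02))
})

test_that("zero atrial amplitude yields identically zero ground truth", {
  sim <- simulate_af_ecg(af_ecg_params(duration_s = 4, seed = 5,
    f_wave_amplitude_per_lead = setNames(rep(0, 12), ECG_LEADS_12)))
  expect_true(all(sim$atrial == 0))
})

test_that("generation is deterministic in the seed", {
  a <- simulate_af_ecg(af_ecg_params(duration_s = 4, seed = 42))
  b <- simulate_af_ecg(af_ecg_params(duration_s = 4, seed = 42))
  expect_identical(a$record$signals, b$record$signals)
  expect_identical(a$atrial, b$atrial)
  expect_identical(a$r_times_s, b$r_times_s)
  c <- simulate_af_ecg(af_ecg_params(duration_s = 4, seed = 43))
  expect_false(identical(a$record$signals, c$record$signals))
})

test_that("record decomposes exactly into its simulated components", {
  sim <- simulate_af_ecg(af_ecg_params(duration_s = 4, seed = 9))
  nonatrial <- sim$record$signals - sim$atrial
  # atrial + ventricular + common-mode wander/mains + noise: removing the
  # two per-lead matrices leaves a lead-independent part plus iid noise
  resid <- nonatrial - sim$ventricular
  # the wander+mains common term is identical across leads up to the noise
  spread <- apply(resid, 1, max) - apply(resid, 1, min)
  expect_lt(max(spread), 8 * sim$params$noise_sd)
  # and with noise off the decomposition is sample-exact
  sim0 <- simulate_af_ecg(af_ecg_params(duration_s = 4, seed = 9,
                                        noise_sd = 0))
  resid0 <- sim0$record$signals - sim0$atrial - sim0$ventricular
  expect_equal(resid0[, 1], resid0[, 12], tolerance = 1e-15)
})

test_that("atrial spectrum peaks at the fibrillatory frequency", {
  for (f0 in c(4.5, 6, 8)) {
    sim <- simulate_af_ecg(af_ecg_params(duration_s = 30, seed = 2,
                                         f_wave_freq = f0,
                                         f_freq_jitter = 0.02))
    x <- sim$atrial[, "V1"]
    sp <- Mod(stats::fft(x - mean(x)))^2
    freqs <- (seq_along(sp) - 1) * 2000 / length(sp)
    keep <- freqs > 1 & freqs < 20
    fpeak <- freqs[keep][which.max(sp[keep])]
    expect_lt(abs(fpeak - f0), 0.3)
  }
})

test_that("RR intervals respect the refractory floor and requested mean", {
  sim <- simulate_af_ecg(af_ecg_params(duration_s = 60, seed = 21))
  rr <- diff(sim$r_times_s)
  expect_true(all(rr >= 0.25))
  expect_lt(abs(mean(rr) - 0.8), 0.1)
})

test_that("cohort generator honors group sizes and degenerate reductions", {
  co <- simulate_cohort(cohort_sim_params(n_success = 0, n_failure = 5,
                                          seed = 3))
  expect_equal(nrow(co), 5L)
  expect_true(all(co$outcome == "FAILURE"))

  co2 <- simulate_cohort(cohort_sim_params(
    n_success = 6, n_failure = 4,
    reduction_success = list(mean = 5, sd = 0),
    reduction_failure = list(mean = 16, sd = 0), seed = 3))
  dec <- 100 * (1 - co2$meanfwa_endwpvi / co2$meanfwa_baseline)
  expect_equal(dec[co2$outcome == "SUCCESS"], rep(5, 6), tolerance = 1e-9)
  expect_equal(dec[co2$outcome == "FAILURE"], rep(16, 4), tolerance = 1e-9)
})

test_that("cohort group medians match the generator targets over replicates", {
  p <- cohort_sim_params(n_success = 54, n_failure = 26)
  meds <- vapply(1:200, function(s) {
    co <- simulate_cohort(cohort_sim_params(n_success = 54, n_failure = 26,
                                            seed = s))
    c(s = median(co$meanfwa_baseline[co$outcome == "SUCCESS"]),
      f = median(co$meanfwa_baseline[co$outcome == "FAILURE"]))
  }, numeric(2))
  expect_equal(mean(meds["s", ]), p$baseline_meanfwa_success$median,
               tolerance = 0.02)
  expect_equal(mean(meds["f", ]), p$baseline_meanfwa_failure$median,
               tolerance = 0.02)
})

test_that("per-patient lead profile averages to the patient meanfwa exactly", {
  co <- simulate_cohort(cohort_sim_params(n_success = 5, n_failure = 5,
                                          seed = 11))
  leadcols <- grep("^fwa_.*_baseline$", names(co), value = TRUE)
  expect_equal(rowMeans(as.data.frame(co)[leadcols]), co$meanfwa_baseline,
               tolerance = 1e-12, ignore_attr = TRUE)
})
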