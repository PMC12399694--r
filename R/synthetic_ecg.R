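# Synthetic 12-lead AF ECG with analytic atrial ground truth.
#
# The atrial (fibrillatory) component is the classic sawtooth-harmonic
# surface-AF model: a truncated sawtooth of >= 3 harmonics whose
# peak-to-trough amplitude is set exactly per lead, with cycle-to-cycle
# frequency jitter and slow sinusoidal amplitude modulation. Ventricular
# activity is a per-beat template (Gaussian Q/R/S lobes + raised-cosine T)
# placed at i.i.d. lognormal RR intervals with a 0.25-s refractory floor.
# Record = atrial + ventricular + baseline wander + 50 Hz mains + white
# noise, so each component is available sample-exactly as ground truth.

#' Per-lead atrial peak-to-trough amplitude defaults (mV)
#'
#' Largest on III, smallest on the back electrode V6b; 12-lead mean
#' ~0.041 mV.
#' @export
DEFAULT_FWAVE_AMP <- c(I = 0.030, II = 0.045, III = 0.064, aVR = 0.036,
                       aVL = 0.030, aVF = 0.050, V1 = 0.050, V2 = 0.048,
                       V3 = 0.045, V4 = 0.040, V5 = 0.034, V6b = 0.018)

# Per-lead ventricular scaling (dimensionless, applied to qrs/t amplitude).
DEFAULT_VENT_SCALE <- c(I = 0.7, II = 1.0, III = 0.6, aVR = -0.9, aVL = 0.35,
                        aVF = 0.8, V1 = -0.6, V2 = 1.1, V3 = 1.2, V4 = 1.0,
                        V5 = 0.85, V6b = 0.45)

#' Parameters for the synthetic AF ECG generator
#'
#' @param fs sampling rate, Hz.
#' @param duration_s record length, seconds.
#' @param f_wave_amplitude_per_lead named numeric, per-lead atrial
#'   peak-to-trough amplitude in mV (before modulation).
#' @param f_wave_freq atrial (fibrillatory) rate in Hz; physiological range
#'   4-9 Hz.
#' @param n_harmonics number of sawtooth harmonics (>= 3).
#' @param f_freq_jitter relative SD of cycle-to-cycle frequency.
#' @param amp_modulation_depth fractional depth of a slow (0.2 Hz) sinusoidal
#'   amplitude modulation of the atrial component.
#' @param mean_rr_s,rr_cv mean and coefficient of variation of the lognormal
#'   RR intervals (AF-like irregularity).
#' @param qrs_amplitude,t_amplitude R-wave and T-wave amplitudes in mV on the
#'   reference lead (scaled per lead).
#' @param baseline_wander_amp,mains_amp,noise_sd amplitudes (mV) of the
#'   sub-0.5 Hz wander, 50 Hz interference, and white noise.
#' @param seed integer RNG seed.
#' @return a list of class `af_ecg_params`.
#' @export
af_ecg_params <- function(fs = 2000, duration_s = 60,
                          f_wave_amplitude_per_lead = DEFAULT_FWAVE_AMP,
                          f_wave_freq = 6, n_harmonics = 5,
                          f_freq_jitter = 0.05, amp_modulation_depth = 0.1,
                          mean_rr_s = 0.8, rr_cv = 0.2,
                          qrs_amplitude = 1.0, t_amplitude = 0.3,
                          baseline_wander_amp = 0.05, mains_amp = 0.02,
                          noise_sd = 0.005, seed = 1L) {
  p <- list(fs = fs, duration_s = duration_s,
            f_wave_amplitude_per_lead = f_wave_amplitude_per_lead,
            f_wave_freq = f_wave_freq, n_harmonics = n_harmonics,
            f_freq_jitter = f_freq_jitter,
            amp_modulation_depth = amp_modulation_depth,
            mean_rr_s = mean_rr_s, rr_cv = rr_cv,
            qrs_amplitude = qrs_amplitude, t_amplitude = t_amplitude,
            baseline_wander_amp = baseline_wander_amp, mains_amp = mains_amp,
            noise_sd = noise_sd, seed = as.integer(seed))
  stopifnot(p$fs > 0, p$duration_s > 0,
            all(p$f_wave_amplitude_per_lead >= 0),
            p$rr_cv >= 0, p$rr_cv < 1,
            p$f_wave_freq > 0, p$f_wave_freq < p$fs / 2,
            p$n_harmonics >= 3)
  if (p$f_wave_freq * p$n_harmonics >= p$fs / 2)
    stop("f_wave_freq x n_harmonics must stay below the Nyquist rate")
  class(p) <- "af_ecg_params"
  p
}

#' Named generator presets
#'
#' `clean` has no ventricular activity or noise (atrial signal only),
#' `typical` is the default mix (1.0 mV QRS over 0.02-0.064 mV f-waves),
#' `noisy` doubles wander/mains/noise.
#' @param preset preset name.
#' @param ... overrides passed to [af_ecg_params()].
#' @export
af_ecg_preset <- function(preset = c("typical", "clean", "noisy"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    typical = list(),
    clean = list(qrs_amplitude = 0, t_amplitude = 0,
                 baseline_wander_amp = 0, mains_amp = 0, noise_sd = 0),
    noisy = list(baseline_wander_amp = 0.1, mains_amp = 0.05,
                 noise_sd = 0.01))
  do.call(af_ecg_params, utils::modifyList(base, list(...)))
}

# Truncated sawtooth evaluated at phase ph (radians), unit-normalized so that
# its peak-to-trough over a full cycle is exactly 1.
sawtooth_unit <- function(ph, n_harmonics) {
  s <- 0
  for (k in seq_len(n_harmonics)) s <- s + (-1)^(k + 1) / k * sin(k * ph)
  ref <- 0
  phg <- seq(0, 2 * pi, length.out = 4096L)
  for (k in seq_len(n_harmonics)) ref <- ref + (-1)^(k + 1) / k * sin(k * phg)
  s / (max(ref) - min(ref))
}

#' Simulate a 12-lead AF ECG with known atrial ground truth
#'
#' @param params an [af_ecg_params()] (or preset).
#' @return a list with `record` (the composite [ecg_record()]), `atrial`
#'   (ground-truth atrial-only matrix, mV), `ventricular` (QRST-only matrix),
#'   `r_times_s` (true R-peak times, seconds), and `params`.
#' @export
simulate_af_ecg <- function(params = af_ecg_params()) {
  stopifnot(inherits(params, "af_ecg_params"))
  p <- params
  n <- round(p$fs * p$duration_s)
  t <- (seq_len(n) - 1L) / p$fs
  amp <- p$f_wave_amplitude_per_lead
  leads <- names(amp)
  if (is.null(leads)) leads <- ECG_LEADS_12[seq_along(amp)]

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(p$seed)

  # atrial phase: piecewise-constant cycle frequency with relative jitter
  n_cycles <- ceiling(p$duration_s * p$f_wave_freq * 1.5) + 2L
  fcyc <- p$f_wave_freq * pmax(0.2, 1 + p$f_freq_jitter * stats::rnorm(n_cycles))
  cyc_dur <- 1 / fcyc
  cyc_end <- cumsum(cyc_dur)
  idx <- findInterval(t, c(0, cyc_end), rightmost.closed = FALSE)
  ph_start <- c(0, 2 * pi * seq_len(n_cycles))
  t_start <- c(0, cyc_end)
  ph <- ph_start[idx] + 2 * pi * fcyc[pmin(idx, n_cycles)] * (t - t_start[idx])
  shape <- sawtooth_unit(ph, p$n_harmonics)
  am <- 1 + p$amp_modulation_depth * sin(2 * pi * 0.2 * t)
  atrial <- outer(shape * am, amp)

  # RR sequence: i.i.d. lognormal with the requested mean/CV, 0.25 s floor
  sdlog <- sqrt(log(1 + p$rr_cv^2))
  mulog <- log(p$mean_rr_s) - sdlog^2 / 2
  rr <- pmax(0.25, stats::rlnorm(ceiling(p$duration_s / 0.25) + 5L,
                                 mulog, sdlog))
  r_times <- cumsum(rr)
  r_times <- r_times[r_times < p$duration_s - 0.05]

  vent1 <- ventricular_trace(t, r_times, p$qrs_amplitude, p$t_amplitude)
  vscale <- DEFAULT_VENT_SCALE[leads]
  vscale[is.na(vscale)] <- 1
  ventricular <- outer(vent1, as.numeric(vscale))

  wander <- p$baseline_wander_amp *
    (sin(2 * pi * 0.22 * t + stats::runif(1, 0, 2 * pi)) +
       0.5 * sin(2 * pi * 0.05 * t + stats::runif(1, 0, 2 * pi)))
  mains <- p$mains_amp * sin(2 * pi * 50 * t + stats::runif(1, 0, 2 * pi))
  common <- wander + mains
  noise <- if (p$noise_sd > 0)
    matrix(stats::rnorm(n * length(amp), 0, p$noise_sd), n) else
    matrix(0, n, length(amp))

  sig <- atrial + ventricular + common + noise
  colnames(atrial) <- colnames(ventricular) <- leads
  list(record = ecg_record(sig, fs = p$fs, lead_labels = leads),
       atrial = atrial, ventricular = ventricular,
       r_times_s = r_times, params = p)
}

# One-lead ventricular trace: Gaussian R lobe with small Q/S side lobes
# (sigma 12 ms) and a raised-cosine T wave centred 220 ms after R.
ventricular_trace <- function(t, r_times, qrs_amp, t_amp) {
  v <- numeric(length(t))
  if (!length(r_times) || (qrs_amp == 0 && t_amp == 0)) return(v)
  fs <- 1 / (t[2L] - t[1L])
  for (rt in r_times) {
    i0 <- max(1L, round((rt - 0.10) * fs) + 1L)
    i1 <- min(length(t), round((rt + 0.45) * fs) + 1L)
    tt <- t[i0:i1] - rt
    qrs <- qrs_amp * (exp(-(tt / 0.012)^2 / 2) -
                        0.15 * exp(-((tt + 0.035) / 0.010)^2 / 2) -
                        0.25 * exp(-((tt - 0.035) / 0.010)^2 / 2))
    tc <- 0.22; tw <- 0.10  # T centre and half-width, s
    twave <- ifelse(abs(tt - tc) < tw,
                    t_amp * 0.5 * (1 + cos(pi * (tt - tc) / tw)), 0)
    v[i0:i1] <- v[i0:i1] + qrs + twave
  }
  v
}

# save/restore the global RNG state so generators are self-seeding without
# disturbing the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
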