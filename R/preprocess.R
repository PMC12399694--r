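# ECG conditioning ahead of atrial-signal extraction: 1-50 Hz band-pass to
# remove baseline wander and mains interference, an optional 50 Hz notch for
# residual interference at the band edge, and polyphase resampling for inputs
# not recorded at 2 kHz. All filtering is zero-phase (forward-backward) so
# envelope amplitudes are not distorted by group delay.

#' Band-pass filter specification
#'
#' @param low_hz high-pass corner (default 1 Hz).
#' @param high_hz low-pass corner (default 50 Hz).
#' @param order Butterworth order of the low-pass stage (the high-pass stage
#'   uses order 2 to stay well-conditioned at very low normalized corners).
#' @param zero_phase apply forward-backward (default TRUE).
#' @param notch_50hz add a 50 Hz IIR notch after the band-pass (default TRUE).
#' @export
filter_spec <- function(low_hz = 1, high_hz = 50, order = 4,
                        zero_phase = TRUE, notch_50hz = TRUE) {
  stopifnot(low_hz > 0, low_hz < high_hz)
  structure(list(low_hz = low_hz, high_hz = high_hz, order = order,
                 zero_phase = zero_phase, notch_50hz = notch_50hz),
            class = "filter_spec")
}

apply_iir <- function(filt, x, zero_phase = TRUE) {
  if (zero_phase) signal::filtfilt(filt, x) else
    as.numeric(signal::filter(filt, x))
}

# second-order IIR notch at f0 with pole radius r (3-dB width ~ (1-r)*fs/pi)
notch_filter <- function(f0, fs, r = 0.985) {
  w0 <- 2 * pi * f0 / fs
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1, -2 * r * cos(w0), r^2)
  b <- b * sum(a) / sum(b)  # unit DC gain
  signal::Arma(b = b, a = a)
}

#' Band-pass filter an ECG record (1-50 Hz default)
#'
#' Implemented as a zero-phase cascade: order-2 Butterworth high-pass at
#' `low_hz` followed by order-`order` Butterworth low-pass at `high_hz`,
#' plus an optional 50 Hz notch. Each lead is filtered independently; output
#' length equals input length and lead means are (numerically) zero.
#'
#' @param record an [ecg_record()].
#' @param spec a [filter_spec()].
#' @return the filtered [ecg_record()].
#' @export
bandpass <- function(record, spec = filter_spec()) {
  stopifnot(inherits(record, "ecg_record"))
  if (record$fs <= 2 * spec$high_hz)
    stop("sampling rate ", record$fs, " Hz too low for a ", spec$high_hz,
         " Hz band edge")
  nyq <- record$fs / 2
  hp <- signal::butter(2, spec$low_hz / nyq, type = "high")
  lp <- signal::butter(spec$order, spec$high_hz / nyq, type = "low")
  nt <- if (spec$notch_50hz && record$fs > 100) notch_filter(50, record$fs)
  out <- apply(record$signals, 2L, function(x) {
    y <- apply_iir(lp, apply_iir(hp, x, spec$zero_phase), spec$zero_phase)
    if (!is.null(nt)) y <- apply_iir(nt, y, spec$zero_phase)
    y
  })
  ecg_record(out, fs = record$fs, lead_labels = record$lead_labels,
             epoch = record$epoch)
}

#' Resample an ECG record to a new rate
#'
#' Fourier-domain band-limited resampling: the spectrum is truncated (which
#' anti-aliases on downsampling) or zero-padded, with linear end-matching to
#' suppress wrap-around transients. Exact for band-limited content away from
#' the record ends; duration is preserved to within one output sample.
#' `target_fs == fs` is the identity.
#'
#' @param record an [ecg_record()].
#' @param target_fs new sampling rate, Hz.
#' @return the resampled [ecg_record()].
#' @export
resample_ecg <- function(record, target_fs) {
  stopifnot(inherits(record, "ecg_record"), target_fs > 0)
  if (target_fs == record$fs) return(record)
  n_in <- nrow(record$signals)
  n_out <- round(n_in * target_fs / record$fs)
  out <- apply(record$signals, 2L, fft_resample, n_out = n_out)
  ecg_record(out, fs = target_fs, lead_labels = record$lead_labels,
             epoch = record$epoch)
}

fft_resample <- function(x, n_out) {
  n <- length(x)
  # detrend the end-to-start jump so the periodic extension is continuous
  ramp <- x[1L] + (x[n] - x[1L]) * (seq_len(n) - 1) / max(1, n - 1)
  base <- x[1L]
  z <- x - ramp
  X <- stats::fft(z)
  Y <- complex(n_out)
  kmax <- min(n, n_out) %/% 2
  Y[seq_len(kmax + 1L)] <- X[seq_len(kmax + 1L)]
  if (kmax > 0)
    Y[n_out + 1L - seq_len(kmax)] <- X[n + 1L - seq_len(kmax)]
  if (n_out %% 2 == 0 && n %% 2 == 0 && kmax == n_out %/% 2)
    Y[kmax + 1L] <- Re(Y[kmax + 1L])  # keep the Nyquist bin real
  y <- Re(stats::fft(Y, inverse = TRUE)) / n
  ramp_out <- base + (x[n] - base) * (seq_len(n_out) - 1) / max(1, n_out - 1)
  y + ramp_out
}
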