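# Ventricular activity suppression. detect_qrs() is an energy detector
# (10-25 Hz band-pass -> squaring -> 150-ms moving-window integration ->
# peak picking with a 250-ms refractory period and a two-cluster height
# split that returns zero beats on homogeneous, QRS-free signals).
# cancel_qrst() then removes ventricular activity beat by beat, treating the
# QRS and T segments separately: for each beat the template is the average
# of the K = 10 nearest-in-time aligned segments, scaled to the beat by a
# single least-squares factor, and the subtraction is blended in with 10-ms
# raised-cosine edges so no steps are introduced. Outside QRST windows the
# signal passes through untouched.

#' Beat annotation container
#' @param r_peaks strictly increasing R-peak sample indices.
#' @param fs sampling rate (Hz) the indices refer to.
#' @param n_samples record length in samples.
#' @param qrs_pre_ms,qrs_post_ms QRS window around R (defaults -60/+80 ms).
#' @param t_dur_ms T/repolarization window length from QRS offset, always
#'   truncated at the next QRS onset. The default `NULL` extends each window
#'   to the next QRS onset: after 1-50 Hz band-pass filtering every beat
#'   contributes a slow beat-locked baseline across the whole inter-beat
#'   interval, and cancelling it requires the template to span it (a fixed
#'   window, e.g. 280 ms, leaves baseline steps at the window edge).
#' @return list of class `beat_annotations` with `r_peaks`, `qrs_windows`
#'   and `t_windows` (2-column matrices of [onset, offset) sample indices).
#' @export
beat_annotations <- function(r_peaks, fs, n_samples,
                             qrs_pre_ms = 60, qrs_post_ms = 80,
                             t_dur_ms = NULL) {
  r_peaks <- sort(as.integer(r_peaks))
  if (length(r_peaks) > 1L && any(diff(r_peaks) < 0.25 * fs))
    stop("R peaks closer than the 0.25-s refractory period")
  pre <- round(qrs_pre_ms / 1000 * fs)
  post <- round(qrs_post_ms / 1000 * fs)
  tdur <- if (is.null(t_dur_ms)) n_samples else round(t_dur_ms / 1000 * fs)
  qon <- pmax(1L, r_peaks - pre)
  qoff <- pmin(n_samples + 1L, r_peaks + post + 1L)
  next_on <- c(qon[-1L], n_samples + 1L)
  ton <- qoff
  toff <- pmin(ton + tdur, next_on, n_samples + 1L)
  structure(list(r_peaks = r_peaks,
                 qrs_windows = cbind(onset = qon, offset = qoff),
                 t_windows = cbind(onset = ton, offset = toff),
                 fs = fs, n_samples = n_samples,
                 qrs_pre = pre, qrs_post = post,
                 t_dur = if (length(r_peaks)) max(toff - ton) else 0L),
            class = "beat_annotations")
}

# single-lead energy detection; returns R-peak sample indices
detect_qrs_lead <- function(x, fs) {
  nyq <- fs / 2
  hp <- signal::butter(2, 10 / nyq, type = "high")
  lp <- signal::butter(2, 25 / nyq, type = "low")
  bp <- signal::filtfilt(lp, signal::filtfilt(hp, x))
  w <- max(3L, round(0.150 * fs))
  z <- as.numeric(stats::filter(bp^2, rep(1 / w, w), sides = 2))
  z[is.na(z)] <- 0
  # local maxima, then greedy acceptance tallest-first with 250-ms spacing
  cand <- which(diff(sign(diff(z))) < 0) + 1L
  if (!length(cand)) return(integer(0))
  cand <- cand[order(z[cand], decreasing = TRUE)]
  acc <- integer(0)
  gap <- round(0.25 * fs)
  for (i in cand) {
    if (!length(acc) || all(abs(acc - i) >= gap)) acc <- c(acc, i)
  }
  h <- z[acc]
  # two-cluster split on peak heights; a homogeneous population means no QRS
  if (length(h) < 2L || max(h) <= 0) return(integer(0))
  lo <- min(h); hi <- max(h)
  for (it in 1:50) {
    assign_hi <- (h - lo)^2 > (h - hi)^2
    lo2 <- mean(h[!assign_hi]); hi2 <- mean(h[assign_hi])
    if (isTRUE(all.equal(c(lo2, hi2), c(lo, hi)))) break
    lo <- lo2; hi <- hi2
  }
  if (!is.finite(lo) || hi / max(lo, .Machine$double.eps) < 4) return(integer(0))
  beats <- sort(acc[(h - lo)^2 > (h - hi)^2])
  # refine each beat to the strongest band-passed deflection nearby
  half <- round(0.08 * fs)
  vapply(beats, function(i) {
    a <- max(1L, i - half); b <- min(length(x), i + half)
    as.integer(a + which.max(abs(bp[a:b])) - 1L)
  }, integer(1))
}

#' Detect ventricular beats
#'
#' Energy-based detection on one lead or, by default, a consensus of leads
#' II, V1 and V4 (R times kept when at least two of the detection leads agree
#' within 100 ms; the consensus time is their median).
#'
#' @param record an [ecg_record()] (band-passed input recommended).
#' @param lead_for_detection a lead label, or `"consensus"`.
#' @return a [beat_annotations()]; zero beats (with a warning) when no
#'   QRS-like activity is found, in which case downstream cancellation is the
#'   identity.
#' @export
detect_qrs <- function(record, lead_for_detection = "consensus") {
  stopifnot(inherits(record, "ecg_record"))
  if (record$duration_s < 2) stop("need at least 2 s of signal")
  n <- nrow(record$signals)
  if (identical(lead_for_detection, "consensus")) {
    want <- intersect(c("II", "V1", "V4"), record$lead_labels)
    if (length(want) < 2L) want <- utils::head(record$lead_labels, 3L)
    det <- lapply(want, function(l)
      detect_qrs_lead(record$signals[, l], record$fs))
    r <- consensus_peaks(det, tol = round(0.1 * record$fs),
                         min_leads = if (length(det) >= 2L) 2L else 1L)
  } else {
    if (!lead_for_detection %in% record$lead_labels)
      stop("unknown detection lead: ", lead_for_detection)
    r <- detect_qrs_lead(record$signals[, lead_for_detection], record$fs)
  }
  # enforce refractory spacing after merging
  if (length(r) > 1L) {
    keep <- c(TRUE, diff(r) >= 0.25 * record$fs)
    while (!all(keep)) { r <- r[keep]; keep <- c(TRUE, diff(r) >= 0.25 * record$fs) }
  }
  if (!length(r)) warning("no beats detected; treating the whole signal as atrial")
  beat_annotations(r, fs = record$fs, n_samples = n)
}

# merge per-lead detections: cluster within tol samples, keep clusters seen
# on >= min_leads leads, take the median time
consensus_peaks <- function(det_list, tol, min_leads = 2L) {
  all_t <- sort(unlist(det_list))
  if (!length(all_t)) return(integer(0))
  src <- unlist(lapply(seq_along(det_list),
                       function(i) rep(i, length(det_list[[i]]))))
  src <- src[order(unlist(det_list))]
  cl <- cumsum(c(1L, as.integer(diff(all_t) > tol)))
  out <- integer(0)
  for (g in unique(cl)) {
    sel <- cl == g
    if (length(unique(src[sel])) >= min_leads)
      out <- c(out, as.integer(round(stats::median(all_t[sel]))))
  }
  sort(out)
}

# segments of x aligned on r_peaks at relative offsets rel; NA outside the
# record, at/after per-beat exclusive end bounds (truncated T windows) or
# before per-beat inclusive start bounds (pre-QRS windows)
extract_segments <- function(x, r_peaks, rel, end_excl = NULL,
                             start_incl = NULL) {
  n <- length(x)
  idx <- outer(r_peaks, rel, "+")
  bad <- idx < 1L | idx > n
  if (!is.null(end_excl)) bad <- bad | idx >= end_excl
  if (!is.null(start_incl)) bad <- bad | idx < start_incl
  idx[bad] <- 1L
  seg <- matrix(x[idx], nrow = length(r_peaks))
  seg[bad] <- NA_real_
  seg
}

# raised-cosine edge taper of total length len; ramps only at the requested
# edges (a window edge that abuts another cancellation window must subtract
# in full there, otherwise the junction is left uncancelled)
edge_taper <- function(len, ramp_n, at_start = TRUE, at_end = TRUE) {
  w <- rep(1, len)
  m <- min(ramp_n, floor(len / 2))
  if (m > 0) {
    ramp <- 0.5 * (1 - cos(pi * (seq_len(m) - 0.5) / m))
    if (at_start) w[seq_len(m)] <- ramp
    if (at_end) w[len + 1L - seq_len(m)] <- pmin(w[len + 1L - seq_len(m)], ramp)
  }
  w
}

# subtract scaled nearest-K templates for one window class on one lead;
# taper_start/taper_end flag, per beat, whether that window edge is free
# (not abutting another cancellation window)
cancel_windows <- function(x, r_peaks, rel, end_excl = NULL,
                           start_incl = NULL, k = 10L, ramp_n,
                           taper_start = TRUE, taper_end = TRUE) {
  nb <- length(r_peaks)
  taper_start <- rep_len(taper_start, nb)
  taper_end <- rep_len(taper_end, nb)
  seg <- extract_segments(x, r_peaks, rel, end_excl, start_incl)
  # the beat's own segment is excluded from its template: averaging it in
  # would subtract a 1/k share of the beat's own atrial activity
  k <- max(1L, min(k, nb - 1L))
  y <- x
  for (b in seq_len(nb)) {
    others <- if (nb > 1L) setdiff(seq_len(nb), b) else b
    nb_idx <- others[order(abs(r_peaks[others] - r_peaks[b]))[seq_len(k)]]
    tmpl <- colMeans(seg[nb_idx, , drop = FALSE], na.rm = TRUE)
    tmpl[is.nan(tmpl)] <- 0
    ok <- !is.na(seg[b, ])
    if (sum(ok) < 4L) next
    den <- sum(tmpl[ok]^2)
    if (den < .Machine$double.eps) next
    a <- sum(seg[b, ok] * tmpl[ok]) / den
    pos <- which(ok)
    w <- edge_taper(length(pos), ramp_n, taper_start[b], taper_end[b])
    smp <- r_peaks[b] + rel[pos]
    y[smp] <- y[smp] - w * a * tmpl[pos]
  }
  y
}

#' Cancel QRST activity, exposing the atrial signal
#'
#' Per lead and per beat, the QRS and T segments are cancelled separately by
#' subtracting an amplitude-scaled average of the K nearest-in-time aligned
#' segments (single least-squares scale per beat and segment class), blended
#' with 10-ms raised-cosine edges. With fewer than 3 beats the template falls
#' back to the global average beat (with a warning); with no beats the signal
#' is returned unchanged.
#'
#' @param record a band-passed [ecg_record()].
#' @param beats a [beat_annotations()] from [detect_qrs()].
#' @param k number of nearest beats averaged into each template.
#' @param ground_truth_atrial optional matrix (same shape as the signals) of
#'   the true atrial component; when given, `residual_ventricular_power` is
#'   power(output - truth) / power(input - truth) per lead, else the ratio of
#'   mean power inside QRS windows to outside.
#' @return list of class `atrial_signal`: `signals` (matrix, mV), `fs`,
#'   `lead_labels`, `beats`, `residual_ventricular_power`.
#' @export
cancel_qrst <- function(record, beats, k = 10L, ground_truth_atrial = NULL) {
  stopifnot(inherits(record, "ecg_record"), inherits(beats, "beat_annotations"))
  x <- record$signals
  n <- nrow(x)
  nb <- length(beats$r_peaks)
  ramp_n <- round(0.010 * record$fs)
  if (nb == 0L) {
    out <- x
  } else {
    if (nb < 3L)
      warning("fewer than 3 beats; using the global average-beat template")
    rel_q <- seq.int(-beats$qrs_pre, beats$qrs_post)
    rel_t <- seq.int(beats$qrs_post + 1L, beats$qrs_post + max(beats$t_dur, 1L))
    t_end <- beats$t_windows[, "offset"]
    # third, next-beat-aligned pass: the band-pass smears each beat's
    # influence backwards in time (zero-phase filtering), leaving a residual
    # locked to the *following* QRS inside the previous beat's T window; a
    # pre-QRS window aligned on each R, applied to the residual of the first
    # two passes, removes it without double subtraction
    pre_ext <- round(0.30 * record$fs)
    rel_p <- seq.int(-(beats$qrs_pre + pre_ext), -(beats$qrs_pre + 1L))
    p_start <- c(1L, beats$qrs_windows[-nb, "offset"])
    # free-edge bookkeeping: QRS onset abuts the previous T window (when
    # tiling), QRS offset always abuts its own T window, a T end is free
    # only when truncated short of the next QRS onset
    qon <- beats$qrs_windows[, "onset"]
    toff <- beats$t_windows[, "offset"]
    q_start_free <- c(TRUE, toff[-nb] < qon[-1L])
    t_end_free <- toff < c(qon[-1L], beats$n_samples + 2L)
    t_nonempty <- beats$t_windows[, "offset"] > beats$t_windows[, "onset"]
    out <- apply(x, 2L, function(xl) {
      y <- cancel_windows(xl, beats$r_peaks, rel_q, k = k, ramp_n = ramp_n,
                          taper_start = q_start_free,
                          taper_end = !t_nonempty)
      y <- cancel_windows(y, beats$r_peaks, rel_t, end_excl = t_end, k = k,
                          ramp_n = ramp_n,
                          taper_start = FALSE, taper_end = t_end_free)
      cancel_windows(y, beats$r_peaks, rel_p, start_incl = p_start, k = k,
                     ramp_n = ramp_n, taper_start = TRUE, taper_end = FALSE)
    })
  }
  colnames(out) <- record$lead_labels
  rvp <- residual_vent_power(x, out, beats, ground_truth_atrial)
  structure(list(signals = out, fs = record$fs,
                 lead_labels = record$lead_labels, beats = beats,
                 epoch = record$epoch,
                 residual_ventricular_power = rvp),
            class = "atrial_signal")
}

residual_vent_power <- function(x, out, beats, truth) {
  if (!is.null(truth)) {
    truth <- as.matrix(truth)
    num <- colSums((out - truth)^2)
    den <- colSums((x - truth)^2)
    return(ifelse(den > 0, num / den, 0))
  }
  if (!length(beats$r_peaks)) return(rep(NA_real_, ncol(x)))
  inq <- logical(nrow(x))
  for (b in seq_len(nrow(beats$qrs_windows)))
    inq[seq.int(beats$qrs_windows[b, 1L],
                beats$qrs_windows[b, 2L] - 1L)] <- TRUE
  apply(out, 2L, function(y)
    mean(y[inq]^2) / max(mean(y[!inq]^2), .Machine$double.eps))
}

#' @export
print.atrial_signal <- function(x, ...) {
  cat(sprintf("<atrial_signal> %d leads x %d samples, %d beats cancelled\n",
              ncol(x$signals), nrow(x$signals), length(x$beats$r_peaks)))
  invisible(x)
}
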