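---
title: "Measuring f-wave amplitude from surface ECGs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring f-wave amplitude from surface ECGs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fwamp)
```

## The measurement problem

During atrial fibrillation the surface ECG is a superposition of a large
ventricular component (QRS complexes and T waves, ~1 mV) and a continuous
atrial oscillation — the f-wave — that is one to two orders of magnitude
smaller (0.02–0.07 mV peak-to-trough) and occupies roughly 4–9 Hz.
`fwamp` estimates the f-wave amplitude (fWA) per lead as the temporal mean
of the distance between the upper and lower envelopes of the atrial
signal, after the ventricular activity has been cancelled. The clinical
quantity of interest is `meanfWA`, the unweighted mean of fWA over the 12
leads (chest lead V6 is recorded on the back, `V6b`, and treated as an
ordinary lead), together with its relative change between a baseline epoch
and the end of a pulmonary-vein-isolation procedure.

## Preprocessing

The band of interest is 1–50 Hz: below 1 Hz lives baseline wander, at
50 Hz mains interference. The band-pass is implemented as a zero-phase
cascade — an order-2 Butterworth high-pass at 1 Hz followed by an order-4
low-pass at 50 Hz, each applied forward–backward — rather than a single
order-4 band-pass: at a 2 kHz sampling rate the normalized low edge
(0.001) makes the 8-pole polynomial filter numerically fragile, while the
cascade is well conditioned and measured flat to 0.1% at 6 Hz with a 1.6%
residual at 0.3 Hz. Zero-phase filtering is chosen because amplitude
fidelity, not causality, is what matters for an envelope metric. A 50 Hz
IIR notch (pole radius 0.985) is on by default since the mains frequency
sits exactly on the band edge. Resampling (for inputs not recorded at
2 kHz) is Fourier-domain band-limited resampling with linear end-matching;
round-trip error on band-limited fixtures is below 1% RMS.

## Beat detection and single-beat QRST cancellation

Beats are detected by a classic energy detector: 10–25 Hz band-pass,
squaring, 150-ms moving-window integration, peak picking with a 250-ms
refractory period. Peak heights are split into two clusters; if the upper
cluster is not at least four times the lower one the signal is declared
QRS-free and the whole record is treated as atrial (this is what makes the
detector return zero beats on atrial-only records instead of firing on
f-wave crests). The default detection is a consensus of leads II, V1 and
V4: an R time is kept when at least two leads agree within 100 ms.

Cancellation treats each beat individually ("single-beat"), with the QRS
and the repolarization segment handled separately. For each beat and each
window class the template is the average of the K = 10 nearest-in-time
aligned segments, scaled to the beat by a single least-squares factor, and
subtracted with 10-ms raised-cosine blending at free window edges. Four
design choices here were forced by measurement against the generator's
ground truth rather than taken from convention:

* **The repolarization window extends to the next QRS onset** (default),
  not a fixed 280 ms. After a 1–50 Hz zero-phase band-pass every beat
  contributes a slow beat-locked baseline across the *entire* inter-beat
  interval (about −0.06 to −0.10 mV for a 1 mV QRS — larger than the
  f-wave itself). A fixed window leaves a step at its edge that inflates
  fWA by tens of percent. A fixed window remains available via
  `t_dur_ms`.
* **Tapers apply only at free edges.** Where a QRS window abuts its T
  window (and a T window abuts the next QRS onset) both windows must
  subtract in full; tapering both sides of the junction leaves a 10-ms
  uncancelled notch of ~0.1–0.2 mV at every beat.
* **A third, next-beat-aligned pass** (300 ms before each QRS onset,
  applied to the residual of the first two passes) removes the acausal
  filter dip that is time-locked to the *following* beat but lies inside
  the previous beat's window, where RR irregularity smears it out of the
  R-aligned template.
* **The beat's own segment is excluded from its template.** With windows
  spanning the full RR interval the least-squares scale locks to ~1, and
  self-inclusion subtracts a 1/K share of the beat's own atrial signal — a
  measured systematic −20% amplitude bias.

With these choices the per-lead fWA measured after cancellation of a 1 mV
QRS stays within ±15% of the value measured on the atrial ground truth
across seeds (typically within ±8%), and residual ventricular power is
~1% of the original.

## Envelope estimation and the 100-ms window

Local extrema are detected "on a 100-ms sliding window". Two readings of
that phrase exist and they are not equivalent:

* **sliding (default):** a sample is an extremum when it dominates the
  100-ms window centred on it — a per-sample sliding window, equivalent to
  a running max/min filter. Every crest of an oscillation slower than
  10 Hz is kept, each at its true height.
* **stepped:** one maximum and one minimum per non-overlapping 100-ms
  window. For a 6 Hz oscillation a 100-ms window spans only 0.6 cycles, so
  a window periodically contains no crest and reports an interior value;
  analytically the expected windowed maximum is ≈ 0.90 of the true
  amplitude, a bias that no later smoothing can undo.

The package defaults to the sliding reading because the stepped one cannot
recover a known amplitude to within the 5% the pipeline commits to; the
stepped mode is retained (`mode = "stepped"`) for comparison. Extremum
series are linearly interpolated onto the uniform sampling grid (edge
values held) and low-pass filtered forward–backward at 2 Hz — below the
4–9 Hz fibrillatory band, above physiological amplitude-modulation rates;
the cutoff is a parameter (`lowpass_hz`). Interpolating before filtering
matters: filtering the irregularly spaced extremum sequence as if it were
uniform would distort the filter's time constants. fWA is floored at zero
(the message notes when flooring triggers), and `measure_fwa(trim =)` can
exclude filter edge effects from the temporal mean.

## Synthetic data: what it emulates and what it does not

`simulate_af_ecg()` builds each lead as *atrial + ventricular + baseline
wander + 50 Hz mains + white noise*, returning every component separately
so each stage has an oracle. The atrial model is the classic
sawtooth-harmonic surface-AF form (5 harmonics by default), with
cycle-to-cycle frequency jitter (5% SD), slow sinusoidal amplitude
modulation (10% at 0.2 Hz), and exact per-lead peak-to-trough scaling —
the per-lead defaults (largest on III at 0.064 mV, smallest on V6b at
0.018 mV, 12-lead mean ≈ 0.041 mV) mirror the amplitude ordering reported
for persistent-AF cohorts. The ventricular model is a Gaussian R lobe with
Q/S side lobes plus a raised-cosine T wave at i.i.d. lognormal RR
intervals (mean 0.8 s, CV 0.2, 0.25-s refractory floor). It deliberately
omits biophysical realism: no AV-nodal memory, no ectopy, no QRS
morphology drift or respiration, no spatially correlated noise. Passing
the recovery tests therefore shows the chain is unbiased under controlled
morphology and stationary amplitude — not that it is robust to every
clinical artifact.

`simulate_cohort()` draws per-patient baseline meanfWA lognormally around
group medians (SUCCESS 0.040 mV, FAILURE 0.038 mV, with log-SDs derived
from quartile pairs), applies a per-patient relative decrease (normal;
SUCCESS mean 5%, FAILURE mean 16%, SD 12) identically to all leads, and
attaches exponential recurrence times (median 12 months in FAILURE)
censored at a 48-month horizon. The defaults are fixed once to mimic the
reported group structure — little baseline separation, clearer separation
after the procedure — and are not adjusted per analysis.

## Statistics layer

The cohort statistics are implemented in-package (base-R and `survival`
equivalents serve as independent cross-checks in the tests): Mann–Whitney
U with midrank ties, exact two-sided p by the standard two-sample
recursion when n + m ≤ 16 without ties, otherwise normal approximation
with tie and continuity corrections; Fisher's exact two-sided p as the sum
of hypergeometric probabilities not exceeding the observed one; Pearson
chi-squared (1 df, Yates optional); ROC with AUC equal to the normalized U
statistic, DeLong confidence intervals, and the optimal cutoff defined as
max(SE + SP) — ties resolved toward higher sensitivity, then the smaller
threshold; univariate logistic regression by Newton–Raphson on a
standardized predictor with Wald intervals, odds ratios reported per
0.01 mV for amplitude predictors and per percentage point for
relative-change predictors (a 1 mV increment would be meaningless at
f-wave scale); Kaplan–Meier and the two-group log-rank test. Degenerate
inputs are flagged rather than silently handled: constant predictors and
(quasi-)separation return non-finite odds ratios with warnings, zero
Fisher margins return p = 1 with a warning.

## The two-threshold outcome rule

`classify()` predicts SUCCESS when baseline meanfWA ≥ 0.044 mV **or** the
relative decrease ≤ 11%; both comparisons are inclusive and an amplitude
increase (negative decrease) always predicts SUCCESS. "Decrease" is the
sign-flipped relative change, so a fall in amplitude is positive.
`fit_rule()` learns both thresholds by a two-stage ROC procedure: the
baseline cutoff first, then — among patients below it — the decrease
cutoff. How the original thresholds were derived is not specified in the
source literature; the two-stage procedure is this package's documented
interpretation. One guard is added: the decrease branch is kept only when
it improves SE + SP on the fitting cohort, otherwise its cutoff is set
below every observed decrease (the branch is inert). Without the guard, a
degenerate second stage (for example a single class below the baseline
cutoff, with the prescribed fallback to the marginal cutoff) can label
every patient SUCCESS and make the fitted two-branch rule *worse* than its
own first stage.

## Problem sizes and numerical tolerances

The validation suite uses 60-s, 12-lead records at 2 kHz for pipeline
recovery (20 seeds), 20-s single-lead records for amplitude linearity,
5000 replicates for the Mann–Whitney size check (n = 20 per arm, accepted
in [0.03, 0.07] at nominal 0.05), and 1000 replicates for logistic slope
coverage (accepted ≥ 93% within 2 SE). Amplitude recovery on ventricle-free
records is required within ±5% over 0.02–0.08 mV; with QRST cancellation,
within ±15% per lead. Envelope and equivariance checks tolerate filter
edge effects by trimming 5–10% of the record ends. Exact oracle
equivalences (Fisher enumeration for all 2×2 tables with n ≤ 30, AUC–U
identity, cutoff search, product-limit arithmetic) are asserted to
1e-12.

## Known limitations

* Cancellation quality is assessed against synthetic morphology; real
  recordings add ectopic beats, QRS morphology changes and electrode
  artifacts that the single-scalar template scaling does not model.
* fWA is the only atrial metric: no dominant frequency, organization
  index or entropy measures.
* The EDF format is not read (no suitable reader available); CSV is the
  canonical interchange format and a minimal WFDB format-16 reader/writer
  is provided.
* The logistic layer is univariate by design; no multivariable or
  adjusted models.
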