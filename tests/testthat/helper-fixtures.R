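# shared fixtures, generated in code

# short clean atrial-only record (no ventricular activity, noise or jitter)
clean_atrial <- function(duration_s = 10, amp = DEFAULT_FWAVE_AMP, seed = 3,
                         ...) {
  simulate_af_ecg(af_ecg_preset("clean", duration_s = duration_s,
                                f_wave_amplitude_per_lead = amp,
                                amp_modulation_depth = 0, f_freq_jitter = 0,
                                seed = seed, ...))
}

# pure sinusoid record at frequency f and (half-)amplitude a, mV
sine_record <- function(a = 0.025, f = 6, fs = 2000, duration_s = 10,
                        leads = "V1") {
  t <- (seq_len(fs * duration_s) - 1) / fs
  sig <- matrix(rep(a * sin(2 * pi * f * t), length(leads)), ncol = length(leads))
  ecg_record(sig, fs = fs, lead_labels = leads)
}

# tiny hand-made cohort with explicit meanfwa/decrease values
mini_cohort <- function(baseline, decrease, outcome,
                        id = sprintf("P%02d", seq_along(baseline))) {
  cohort_table(data.frame(patient_id = id, outcome = outcome,
                          meanfwa_baseline = baseline,
                          meanfwa_endwpvi = baseline * (1 - decrease / 100),
                          decrease_pct = decrease,
                          stringsAsFactors = FALSE))
}
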