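# Minimal WFDB support: text .hea header plus format-16 .dat (interleaved
# little-endian int16). Covers exactly what the pipeline writes; amplitudes
# are stored at a fixed gain in ADC units per mV and returned in mV.

FWAMP_WFDB_GAIN <- 10000  # adu/mV; int16 span then covers +/-3.27 mV

read_ecg_wfdb <- function(path, epoch = "other") {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("file not found: ", hea)
  lines <- readLines(hea)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  rec <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  nsig <- as.integer(rec[2L])
  fs <- as.numeric(rec[3L])
  nsamp <- as.integer(rec[4L])
  sig <- lapply(lines[1L + seq_len(nsig)], function(l) strsplit(trimws(l), "\\s+")[[1L]])
  datfile <- vapply(sig, `[`, "", 1L)
  if (length(unique(datfile)) != 1L)
    stop("multi-file WFDB records are not supported")
  fmt <- vapply(sig, `[`, "", 2L)
  if (any(sub("x.*", "", fmt) != "16"))
    stop("only WFDB format 16 is supported")
  gainfield <- vapply(sig, `[`, "", 3L)
  gain <- as.numeric(sub("\\(.*", "", sub("/.*", "", gainfield)))
  baseline <- ifelse(grepl("\\(", gainfield),
                     as.numeric(sub(".*\\((-?[0-9]+)\\).*", "\\1", gainfield)), 0)
  labels <- vapply(sig, function(f) f[length(f)], "")
  dat <- file.path(dirname(hea), datfile[1L])
  raw <- readBin(dat, "integer", n = nsig * nsamp, size = 2L,
                 signed = TRUE, endian = "little")
  m <- matrix(raw, ncol = nsig, byrow = TRUE)
  mv <- sweep(sweep(m, 2L, baseline, "-"), 2L, gain, "/")
  ecg_record(mv, fs = fs, lead_labels = labels, epoch = epoch)
}

write_ecg_wfdb <- function(record, path, gain = FWAMP_WFDB_GAIN) {
  path <- sub("\\.hea$", "", path)
  name <- basename(path)
  n <- nrow(record$signals); nsig <- ncol(record$signals)
  adc <- round(record$signals * gain)
  if (any(abs(adc) > 32767))
    stop("signal exceeds the int16 range at gain ", gain, " adu/mV")
  hea <- c(
    sprintf("%s %d %g %d", name, nsig, record$fs, n),
    sprintf("%s.dat 16 %g(0)/mV 16 0 %d 0 0 %s",
            name, gain, as.integer(adc[1L, ]), record$lead_labels)
  )
  writeLines(hea, paste0(path, ".hea"))
  writeBin(as.integer(t(adc)), paste0(path, ".dat"), size = 2L,
           endian = "little")
  invisible(path)
}
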