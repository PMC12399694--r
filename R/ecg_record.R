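#' Standard 12-lead labels used throughout the pipeline
#'
#' Chest lead V6 is relocated to the patient's back ("V6b") to better capture
#' left-atrial activity; it is treated as an ordinary 12th lead with no
#' positional semantics beyond its name.
#' @export
ECG_LEADS_12 <- c("I", "II", "III", "aVR", "aVL", "aVF",
                  "V1", "V2", "V3", "V4", "V5", "V6b")

#' Construct a multi-lead ECG record
#'
#' The basic container consumed by every pipeline stage: uniformly sampled
#' voltage series for one or more leads, all in millivolts.
#'
#' @param signals numeric matrix, samples x leads, in mV. Column names, if
#'   present, are used as lead labels.
#' @param fs sampling rate in Hz (the pipeline default is 2000 Hz).
#' @param lead_labels character vector of unique lead names; defaults to the
#'   column names of `signals` or `ECG_LEADS_12` truncated to the lead count.
#' @param epoch one of `"baseline"`, `"endWPVI"`, `"other"`.
#' @return an object of class `ecg_record` with fields `signals`, `fs`,
#'   `lead_labels`, `epoch`, `duration_s`.
#' @export
ecg_record <- function(signals, fs, lead_labels = NULL, epoch = "other") {
  signals <- as.matrix(signals)
  storage.mode(signals) <- "double"
  if (is.null(lead_labels)) {
    lead_labels <- colnames(signals)
    if (is.null(lead_labels)) {
      lead_labels <- if (ncol(signals) == 12L) ECG_LEADS_12 else
        paste0("L", seq_len(ncol(signals)))
    }
  }
  if (length(lead_labels) != ncol(signals))
    stop("lead_labels length (", length(lead_labels),
         ") does not match lead count (", ncol(signals), ")")
  if (anyDuplicated(lead_labels))
    stop("duplicated lead labels: ",
         paste(unique(lead_labels[duplicated(lead_labels)]), collapse = ", "))
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number (Hz)")
  epoch <- match.arg(epoch, c("baseline", "endWPVI", "other"))
  bad <- which(!is.finite(signals), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-finite sample in lead '", lead_labels[bad[1L, 2L]],
         "' at index ", bad[1L, 1L])
  colnames(signals) <- lead_labels
  structure(
    list(signals = signals, fs = fs, lead_labels = lead_labels,
         epoch = epoch, duration_s = nrow(signals) / fs),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %d leads x %d samples, fs = %g Hz (%.3f s), epoch = %s\n",
              ncol(x$signals), nrow(x$signals), x$fs, x$duration_s, x$epoch))
  cat("  leads:", paste(x$lead_labels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ecg_record <- function(x) dim(x$signals)

#' Read a multi-lead ECG recording
#'
#' Dispatches on `format`: `"csv"` expects a header row of lead labels and one
#' column per lead with samples in mV (the sampling rate is not stored in the
#' file and must be supplied); `"wfdb"` reads a WFDB header/signal pair
#' written by [write_ecg()] (16-bit format, gains applied so the returned
#' values are mV). `"auto"` infers from the file extension.
#'
#' @param path path to the `.csv` file or the WFDB record name (with or
#'   without `.hea`).
#' @param format one of `"auto"`, `"csv"`, `"wfdb"`.
#' @param fs sampling rate in Hz; required for CSV, ignored for WFDB (taken
#'   from the header).
#' @param epoch epoch label to attach.
#' @return an [ecg_record()].
#' @export
read_ecg <- function(path, format = c("auto", "csv", "wfdb"), fs = NULL,
                     epoch = "other") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv"
              else if (grepl("\\.hea$", path) || file.exists(paste0(path, ".hea"))) "wfdb"
              else if (grepl("\\.edf$", path, ignore.case = TRUE))
                stop("EDF input is not supported; convert to CSV or WFDB first")
              else stop("cannot infer ECG format from path: ", path)
  }
  if (format == "csv") {
    if (!file.exists(path)) stop("file not found: ", path)
    if (is.null(fs)) stop("fs (Hz) is required when reading CSV ECGs")
    df <- utils::read.csv(path, check.names = FALSE)
    ecg_record(as.matrix(df), fs = fs, lead_labels = names(df), epoch = epoch)
  } else {
    read_ecg_wfdb(path, epoch = epoch)
  }
}

#' Write a multi-lead ECG recording
#'
#' @param record an [ecg_record()].
#' @param path output path (CSV) or WFDB record name (no extension).
#' @param format `"csv"` or `"wfdb"`.
#' @return `path`, invisibly.
#' @export
write_ecg <- function(record, path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  stopifnot(inherits(record, "ecg_record"))
  if (format == "csv") {
    df <- as.data.frame(record$signals)
    names(df) <- record$lead_labels
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    write_ecg_wfdb(record, path)
  }
  invisible(path)
}
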