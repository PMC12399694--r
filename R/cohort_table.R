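COHORT_OUTCOMES <- c("SUCCESS", "FAILURE", "ON_AAD", "EXCLUDED")

#' Validate (and complete) a per-patient cohort table
#'
#' Expected columns: `patient_id`, `outcome` (one of SUCCESS, FAILURE,
#' ON_AAD, EXCLUDED), optional `followup_months` and `event` (0/1), then
#' `fwa_<LEAD>_baseline` / `fwa_<LEAD>_endwpvi` per lead in mV. The two
#' aggregate columns `meanfwa_baseline` / `meanfwa_endwpvi` are recomputed
#' from the per-lead columns when absent.
#'
#' @param df a data.frame.
#' @return the validated data.frame with class `c("cohort_table",
#'   "data.frame")` and both meanfwa columns present.
#' @export
cohort_table <- function(df) {
  stopifnot(is.data.frame(df))
  req <- c("patient_id", "outcome")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("cohort is missing columns: ", paste(miss, collapse = ", "))
  df$patient_id <- as.character(df$patient_id)
  dup <- unique(df$patient_id[duplicated(df$patient_id)])
  if (length(dup)) stop("duplicated patient_id: ", paste(dup, collapse = ", "))
  bad <- setdiff(unique(df$outcome), COHORT_OUTCOMES)
  if (length(bad)) stop("unknown outcome label(s): ", paste(bad, collapse = ", "))
  if ("followup_months" %in% names(df)) {
    neg <- df$followup_months < 0 & !is.na(df$followup_months)
    if (any(neg)) stop("negative follow-up time for patient(s): ",
                       paste(df$patient_id[neg], collapse = ", "))
  }
  if ("event" %in% names(df) &&
      !all(df$event %in% c(0, 1, NA)))
    stop("event must be 0/1")
  for (ep in c("baseline", "endwpvi")) {
    leads <- cohort_lead_columns(df, ep)
    mcol <- paste0("meanfwa_", ep)
    if (length(leads) && !(mcol %in% names(df)))
      df[[mcol]] <- rowMeans(df[, leads, drop = FALSE])
  }
  class(df) <- c("cohort_table", "data.frame")
  df
}

cohort_lead_columns <- function(df, epoch = c("baseline", "endwpvi")) {
  epoch <- match.arg(epoch)
  grep(paste0("^fwa_.+_", epoch, "$"), names(df), value = TRUE)
}

#' Read a cohort CSV
#' @param path CSV path (see [cohort_table()] for the schema).
#' @return a validated `cohort_table`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cohort_table(utils::read.csv(path, check.names = FALSE,
                               stringsAsFactors = FALSE))
}

#' Write a cohort table to CSV
#' @param cohort a `cohort_table` (or plain data.frame with the schema).
#' @param path output path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' Endpoint breakdown of a cohort
#'
#' Counts and percentage shares of each outcome label among analyzed patients
#' (EXCLUDED rows are dropped first), mirroring how ablation studies report
#' their patient flow: long-term sinus rhythm off antiarrhythmic drugs
#' (SUCCESS), rhythm controlled on drugs (ON_AAD), and recurrence despite
#' durable isolation (FAILURE).
#'
#' @param cohort a `cohort_table` or data.frame with an `outcome` column.
#' @return data.frame with columns `outcome`, `n`, `pct` (percent of the
#'   analyzed total).
#' @export
outcome_summary <- function(cohort) {
  oc <- cohort$outcome[cohort$outcome != "EXCLUDED"]
  lev <- intersect(COHORT_OUTCOMES, unique(oc))
  n <- vapply(lev, function(l) sum(oc == l), 0L)
  data.frame(outcome = lev, n = as.integer(n),
             pct = 100 * as.integer(n) / length(oc),
             row.names = NULL)
}
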