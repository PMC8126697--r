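COHORT_COLUMNS <- c("patient", "age", "gender", "implantation_site",
                    "n_days", "n_ieeg_files", "n_ictal_patterns")

#' Load a per-patient recording-metadata table
#'
#' Reads a CSV with one row per implanted patient and columns
#' `patient, age, gender, implantation_site, n_days, n_ieeg_files,
#' n_ictal_patterns`. The package ships the demographics and device-data
#' summary of the 22-patient RNS cohort it models as
#' `system.file("extdata", "rns_cohort.csv", package = "ictalnet")`.
#'
#' @param path CSV path; defaults to the packaged cohort table.
#' @return a validated `data.frame` of class `recording_metadata`.
#' @export
load_cohort_table <- function(path = system.file("extdata", "rns_cohort.csv",
                                                 package = "ictalnet")) {
  if (!file.exists(path)) stop_fmt("no such file: %s", path)
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop_fmt("schema error: %s",
                                              conditionMessage(e)))
  miss <- setdiff(COHORT_COLUMNS, names(df))
  if (length(miss))
    stop_fmt("schema error: missing column(s) %s", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stop_fmt("schema error: empty table")
  df <- df[COHORT_COLUMNS]
  for (col in c("age", "n_days", "n_ieeg_files", "n_ictal_patterns"))
    df[[col]] <- as.integer(df[[col]])
  bad_site <- setdiff(unique(df$implantation_site), IMPLANT_SITES)
  if (length(bad_site))
    stop_fmt("unknown implantation_site: %s", paste(bad_site, collapse = ", "))
  if (!all(df$gender %in% c("F", "M")))
    stop_fmt("gender must be F or M")
  counts <- df[c("n_days", "n_ieeg_files", "n_ictal_patterns")]
  if (any(unlist(counts) < 0)) stop_fmt("counts must be non-negative")
  if (any(df$n_ictal_patterns > df$n_ieeg_files))
    stop_fmt("n_ictal_patterns cannot exceed n_ieeg_files")
  class(df) <- c("recording_metadata", "data.frame")
  df
}

#' Summarize a cohort metadata table
#'
#' Column totals, demographics and the mean recording period
#' (`mean(n_days) / 7`, in weeks). Means are rounded to one decimal for
#' reporting; dispersion is given both as SD and as the standard error of
#' the mean.
#'
#' @param records a `data.frame` as returned by [load_cohort_table()].
#' @return a list of summary statistics.
#' @export
summarize_cohort <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop_fmt("records must be a non-empty metadata table")
  miss <- setdiff(COHORT_COLUMNS, names(records))
  if (length(miss))
    stop_fmt("schema error: missing column(s) %s", paste(miss, collapse = ", "))
  n <- nrow(records)
  weeks <- records$n_days / 7
  list(
    n_patients = n,
    total_recording_days = sum(records$n_days),
    total_ieeg_files = sum(records$n_ieeg_files),
    total_ictal_patterns = sum(records$n_ictal_patterns),
    mean_age = round(mean(records$age), 1),
    sd_age = round(sd(records$age), 1),
    sem_age = round(sd(records$age) / sqrt(n), 1),
    n_female = sum(records$gender == "F"),
    n_male = sum(records$gender == "M"),
    mean_weeks_recording = round(mean(weeks), 1),
    sd_weeks_recording = round(sd(weeks), 1),
    sem_weeks_recording = round(sd(weeks) / sqrt(n), 1))
}

#' Select patients with enough ictal patterns for seed-based testing
#'
#' A patient qualifies for held-out evaluation when more than
#' `max_seed + 5` ictal patterns are available, so that the largest seed
#' set still leaves at least 5 ictal test epochs (strict inequality:
#' exactly `max_seed + 5` is excluded).
#'
#' @param records cohort metadata table.
#' @param max_seed largest seed-set size used (default 30).
#' @return character vector of qualifying patient identifiers.
#' @export
inclusion_filter <- function(records, max_seed = 30) {
  stopifnot(is.data.frame(records),
            all(c("patient", "n_ictal_patterns") %in% names(records)))
  as.character(records$patient[records$n_ictal_patterns > max_seed + 5])
}
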