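# Cohort container and file formats.
#
# A cohort is a plain data.frame with one row per hospitalization and
# list-columns for the multi-valued fields. Within a list-column element,
# character(0) is an observed empty set while NULL marks a missing field
# (e.g. a discharge record that was never filed); see is_missing_set().

#' @name cohort-format
#' @title The cohort data frame
#' @description
#' All psnstrat functions exchange cohorts as data frames with exactly these
#' columns (one row per admission):
#' \describe{
#'   \item{patient_id, admission_id}{opaque identifier strings.}
#'   \item{admission_date}{`Date`.}
#'   \item{age}{integer years; `NA` when unknown.}
#'   \item{sex}{`"male"`, `"female"` or `NA`.}
#'   \item{main_symptoms, general_symptoms, tongue_features, pulse_features,
#'     tcm_diagnoses, icd_codes, herbs, discharge_symptoms}{list-columns of
#'     character vectors; `character(0)` = observed empty, `NULL` = missing.}
#'   \item{outcome}{`"improvement"`, `"discharge"`, `"death"`, `"other"` or
#'     `""` when missing.}
#' }
#' Curated cohorts (after [curate()]) carry an extra `icd_rollup`
#' list-column. On disk a cohort is either CSV, with list fields encoded as
#' `"|"`-delimited strings (`""` = empty set, literal `NA` = missing), or
#' JSON-lines, with list fields as arrays (`[]` = empty, `null` = missing).
NULL

COHORT_LIST_FIELDS <- c(
  "main_symptoms", "general_symptoms", "tongue_features", "pulse_features",
  "tcm_diagnoses", "icd_codes", "herbs", "discharge_symptoms"
)

COHORT_COLUMNS <- c(
  "patient_id", "admission_id", "admission_date", "age", "sex",
  "main_symptoms", "general_symptoms", "tongue_features", "pulse_features",
  "tcm_diagnoses", "icd_codes", "herbs", "discharge_symptoms", "outcome"
)

OUTCOME_LEVELS <- c("improvement", "discharge", "death", "other")

FEATURE_CLASSES <- c("symptom", "tongue", "pulse", "diagnosis", "herb")

validate_cohort <- function(records) {
  if (!is.data.frame(records)) {
    stop_psn("psn_format_error", "a cohort must be a data.frame")
  }
  missing_cols <- setdiff(COHORT_COLUMNS, names(records))
  if (length(missing_cols) > 0) {
    stop_psn("psn_format_error", "cohort is missing columns: %s",
             paste(missing_cols, collapse = ", "))
  }
  dup <- records$admission_id[duplicated(records$admission_id)]
  if (length(dup) > 0) {
    stop_psn("psn_format_error", "duplicate admission_id values: %s",
             paste(unique(dup), collapse = ", "))
  }
  invisible(records)
}

#' Read a cohort of admission records
#'
#' @param path File path; format is inferred from the extension unless given
#'   (`.csv` vs `.jsonl`/`.ndjson`/`.json`).
#' @param format `"auto"`, `"csv"` or `"jsonl"`.
#' @return A cohort data frame (see [cohort-format]).
#' @export
read_records <- function(path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_psn("psn_io_error", "records file not found: %s", path)
  }
  if (format == "auto") {
    format <- if (grepl("\\.(jsonl|ndjson|json)$", path, ignore.case = TRUE)) {
      "jsonl"
    } else {
      "csv"
    }
  }
  if (format == "csv") {
    raw <- utils::read.csv(path, colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
    recs <- decode_csv_cohort(raw)
  } else {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
    recs <- decode_jsonl_cohort(rows)
  }
  validate_cohort(recs)
}

decode_csv_cohort <- function(raw) {
  missing_cols <- setdiff(COHORT_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop_psn("psn_format_error", "records file is missing columns: %s",
             paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(
    patient_id = raw$patient_id,
    admission_id = raw$admission_id,
    admission_date = as.Date(raw$admission_date),
    age = suppressWarnings(as.integer(raw$age)),
    sex = ifelse(nzchar(raw$sex), raw$sex, NA_character_),
    stringsAsFactors = FALSE
  )
  for (f in COHORT_LIST_FIELDS) {
    out[[f]] <- lapply(raw[[f]], function(s) {
      if (is.na(s) || identical(s, "NA")) return(NULL)
      if (!nzchar(s)) return(character(0))
      unique(strsplit(s, "|", fixed = TRUE)[[1]])
    })
  }
  out$outcome <- raw$outcome
  out[COHORT_COLUMNS]
}

decode_jsonl_cohort <- function(rows) {
  get_chr <- function(r, k) {
    v <- r[[k]]
    if (is.null(v) || length(v) == 0) NA_character_ else as.character(v)[1]
  }
  out <- data.frame(
    patient_id = vapply(rows, get_chr, character(1), "patient_id"),
    admission_id = vapply(rows, get_chr, character(1), "admission_id"),
    admission_date = as.Date(vapply(rows, get_chr, character(1),
                                    "admission_date")),
    age = suppressWarnings(as.integer(
      vapply(rows, get_chr, character(1), "age"))),
    sex = vapply(rows, get_chr, character(1), "sex"),
    stringsAsFactors = FALSE
  )
  for (f in COHORT_LIST_FIELDS) {
    out[[f]] <- lapply(rows, function(r) {
      v <- r[[f]]
      if (is.null(v)) return(NULL)
      unique(as.character(v))
    })
  }
  oc <- vapply(rows, get_chr, character(1), "outcome")
  out$outcome <- ifelse(is.na(oc), "", oc)
  out[COHORT_COLUMNS]
}

#' Write a cohort of admission records
#'
#' @param records Cohort data frame.
#' @param path Output path.
#' @param format `"csv"` (list fields `"|"`-delimited, missing encoded as
#'   literal `NA`) or `"jsonl"` (arrays, missing as `null`).
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  cols <- intersect(COHORT_COLUMNS, names(records))
  records <- records[cols]
  if (format == "csv") {
    flat <- records
    for (f in COHORT_LIST_FIELDS) {
      flat[[f]] <- vapply(records[[f]], function(x) {
        if (is_missing_set(x)) "NA" else paste(x, collapse = "|")
      }, character(1))
    }
    flat$admission_date <- as.character(flat$admission_date)
    utils::write.csv(flat, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8", na = "")
  } else {
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(records))) {
      row <- list(
        patient_id = records$patient_id[i],
        admission_id = records$admission_id[i],
        admission_date = as.character(records$admission_date[i]),
        age = records$age[i],
        sex = records$sex[i]
      )
      for (f in COHORT_LIST_FIELDS) {
        v <- records[[f]][[i]]
        row[[f]] <- if (is_missing_set(v)) NULL else as.list(v)
      }
      row$outcome <- records$outcome[i]
      writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, null = "null",
                                  na = "null"), con)
    }
  }
  invisible(path)
}

#' Read a term-normalization dictionary
#'
#' A dictionary is a UTF-8, 3-column, tab-separated file:
#' `raw_term<TAB>canonical_term<TAB>feature_class`, one row per raw term.
#' Feature classes are `symptom`, `tongue`, `pulse`, `diagnosis`, `herb`.
#' Each raw term must map to exactly one canonical term.
#'
#' @param path TSV path.
#' @return A data frame with columns `raw_term`, `canonical_term`,
#'   `feature_class`.
#' @export
read_term_dictionary <- function(path) {
  if (!file.exists(path)) {
    stop_psn("psn_io_error", "dictionary file not found: %s", path)
  }
  d <- utils::read.delim(path, header = FALSE, colClasses = "character",
                         quote = "", fileEncoding = "UTF-8")
  if (ncol(d) != 3) {
    stop_psn("psn_format_error",
             "dictionary must have 3 tab-separated columns, found %d", ncol(d))
  }
  names(d) <- c("raw_term", "canonical_term", "feature_class")
  # tolerate a header row
  if (identical(tolower(d$raw_term[1]), "raw_term")) d <- d[-1, , drop = FALSE]
  validate_term_dictionary(d)
}

validate_term_dictionary <- function(d) {
  if (any(!nzchar(d$canonical_term))) {
    stop_psn("psn_format_error", "dictionary has empty canonical terms")
  }
  bad_class <- setdiff(unique(d$feature_class), FEATURE_CLASSES)
  if (length(bad_class) > 0) {
    stop_psn("psn_format_error", "unknown feature classes in dictionary: %s",
             paste(bad_class, collapse = ", "))
  }
  dup <- d$raw_term[duplicated(d$raw_term)]
  if (length(dup) > 0) {
    stop_psn("psn_format_error",
             "dictionary maps raw terms more than once: %s",
             paste(unique(dup), collapse = ", "))
  }
  rownames(d) <- NULL
  d
}

#' Write a term-normalization dictionary
#'
#' @param dictionary Data frame as returned by [read_term_dictionary()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_term_dictionary <- function(dictionary, path) {
  utils::write.table(
    dictionary[c("raw_term", "canonical_term", "feature_class")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE,
    fileEncoding = "UTF-8"
  )
  invisible(path)
}
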