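# Curation: term normalization, ICD rollup, inclusion/exclusion.

# Which dictionary feature class is allowed in each multi-valued field.
# Discharge symptoms are symptoms; icd_codes bypass the dictionary entirely
# (they are rolled up, not normalized).
FIELD_CLASS <- c(
  main_symptoms = "symptom",
  general_symptoms = "symptom",
  discharge_symptoms = "symptom",
  tongue_features = "tongue",
  pulse_features = "pulse",
  tcm_diagnoses = "diagnosis",
  herbs = "herb"
)

#' Normalize free-text terms to the canonical vocabulary
#'
#' Maps every raw term in the multi-valued fields (except `icd_codes`) to
#' its canonical form through the dictionary and de-duplicates the result,
#' so records become comparable set-valued phenotypes. A term whose
#' dictionary class disagrees with the field it sits in (e.g. a herb inside
#' `pulse_features`) is always an error; an *unmapped* term is an error
#' under `policy = "strict"` and is dropped (and tallied) under
#' `policy = "drop_unknown"`.
#'
#' @param records Cohort data frame (see [cohort-format]).
#' @param dictionary Term dictionary data frame ([read_term_dictionary()]).
#' @param policy `"drop_unknown"` (default) or `"strict"`.
#' @return A list with `records` (normalized cohort, plus an `icd_rollup`
#'   list-column from [rollup_icd()]) and `unmapped` (data frame of
#'   `raw_term`, `count` for terms dropped under `drop_unknown`).
#' @export
normalize_terms <- function(records, dictionary,
                            policy = c("drop_unknown", "strict")) {
  policy <- match.arg(policy)
  validate_cohort(records)
  canonical_of <- stats::setNames(dictionary$canonical_term,
                                  dictionary$raw_term)
  class_of <- stats::setNames(dictionary$feature_class, dictionary$raw_term)
  # canonical terms are valid input too (idempotence): extend the lookup
  # with identity rows for canonical terms not already present as raw terms
  canon <- unique(dictionary[c("canonical_term", "feature_class")])
  extra <- canon[!(canon$canonical_term %in% names(canonical_of)), ,
                 drop = FALSE]
  if (nrow(extra) > 0) {
    canonical_of <- c(canonical_of,
                      stats::setNames(extra$canonical_term,
                                      extra$canonical_term))
    class_of <- c(class_of,
                  stats::setNames(extra$feature_class, extra$canonical_term))
  }
  unmapped <- new.env(parent = emptyenv())
  out <- records
  for (field in names(FIELD_CLASS)) {
    want <- FIELD_CLASS[[field]]
    out[[field]] <- lapply(records[[field]], function(terms) {
      if (is_missing_set(terms)) return(NULL)
      terms <- as_term_set(terms) %||% character(0)
      known <- terms %in% names(canonical_of)
      if (any(!known)) {
        if (policy == "strict") {
          stop_psn("psn_normalization_error",
                   "unmapped term(s) in %s: %s", field,
                   paste(terms[!known], collapse = ", "))
        }
        for (t in terms[!known]) {
          assign(t, (get0(t, envir = unmapped) %||% 0) + 1, envir = unmapped)
        }
        terms <- terms[known]
      }
      bad <- terms[class_of[terms] != want]
      if (length(bad) > 0) {
        stop_psn("psn_classification_error",
                 "term(s) of class %s found in field %s: %s",
                 paste(unique(class_of[bad]), collapse = "/"), field,
                 paste(bad, collapse = ", "))
      }
      unique(unname(canonical_of[terms]))
    })
  }
  out$icd_rollup <- lapply(records$icd_codes, function(codes) {
    if (is_missing_set(codes)) return(NULL)
    rollup_icd(as_term_set(codes) %||% character(0))
  })
  terms <- ls(unmapped)
  unmapped_df <- data.frame(
    raw_term = terms,
    count = vapply(terms, get, numeric(1), envir = unmapped),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (nrow(unmapped_df) > 0) {
    unmapped_df <- unmapped_df[order(-unmapped_df$count,
                                     unmapped_df$raw_term), , drop = FALSE]
    rownames(unmapped_df) <- NULL
  }
  list(records = out, unmapped = unmapped_df)
}

#' Roll up ICD codes to their category level
#'
#' Truncates every code to its category plus at most one character after
#' the decimal point and de-duplicates, so fine-grained clinical extensions
#' collapse onto one higher-level code (e.g. `I50.903` and `I50.905` both
#' become `I50.9`). Codes without a decimal point pass through unchanged.
#'
#' @param codes Character vector of ICD codes.
#' @return Character vector of unique rolled-up codes.
#' @examples
#' rollup_icd(c("I50.903", "I50.905", "K29"))  # "I50.9" "K29"
#' @export
rollup_icd <- function(codes) {
  codes <- as.character(codes)
  codes <- codes[!is.na(codes) & nzchar(codes)]
  unique(sub("^([^.]+\\..).*$", "\\1", codes))
}

COMPLETENESS_FIELDS <- c(
  "main_symptoms", "general_symptoms", "tongue_features", "pulse_features",
  "tcm_diagnoses", "herbs", "discharge_symptoms"
)

#' Score record completeness
#'
#' Counts how many of ten fields are populated: the seven multi-valued
#' clinical fields (`main_symptoms`, `general_symptoms`, `tongue_features`,
#' `pulse_features`, `tcm_diagnoses`, `herbs`, `discharge_symptoms`) plus
#' `outcome`, `age` and `sex`. Used to pick the most complete admission when
#' a patient was hospitalized more than once.
#'
#' @param records Cohort data frame.
#' @return Integer vector in 0..10, one score per row.
#' @export
completeness_score <- function(records) {
  validate_cohort(records)
  score <- integer(nrow(records))
  for (f in COMPLETENESS_FIELDS) {
    score <- score + vapply(records[[f]], has_terms, logical(1))
  }
  score <- score +
    (!is.na(records$outcome) & nzchar(records$outcome)) +
    (!is.na(records$age)) +
    (!is.na(records$sex) & nzchar(records$sex))
  as.integer(score)
}

#' Apply the cohort inclusion/exclusion rules
#'
#' Two filters, applied in order: (1) records lacking a patient id, lacking
#' all diagnostic information (`tcm_diagnoses` and `icd_codes` both empty),
#' or lacking a discharge record (`discharge_symptoms` missing/empty and no
#' `outcome`) are excluded as incomplete; (2) when a patient has several
#' surviving admissions, only the one with the highest
#' [completeness_score()] is retained, ties broken by latest
#' `admission_date`, then by lexicographically greatest `admission_id`.
#' The result is one admission per patient.
#'
#' @param records Cohort data frame.
#' @param unmapped Optional unmapped-term data frame (from
#'   [normalize_terms()]) to carry into the report.
#' @return A list with `records` (the included cohort) and `report`, a
#'   `curation_report` whose counts satisfy
#'   `n_input = n_included + n_excluded_missing +
#'   n_excluded_duplicate_admissions`.
#' @export
apply_inclusion_exclusion <- function(records, unmapped = NULL) {
  validate_cohort(records)
  n_input <- nrow(records)
  has_id <- !is.na(records$patient_id) & nzchar(records$patient_id)
  has_dx <- vapply(records$tcm_diagnoses, has_terms, logical(1)) |
    vapply(records$icd_codes, has_terms, logical(1))
  has_discharge <- vapply(records$discharge_symptoms, has_terms, logical(1)) |
    (!is.na(records$outcome) & nzchar(records$outcome))
  keep <- has_id & has_dx & has_discharge
  n_missing <- sum(!keep)
  kept <- records[keep, , drop = FALSE]

  n_dup <- 0L
  if (nrow(kept) > 0) {
    score <- completeness_score(kept)
    # total order: score desc, date desc, admission_id desc
    ord <- order(kept$patient_id, -score, -as.numeric(kept$admission_date),
                 kept$admission_id,
                 method = "radix", decreasing = c(FALSE, FALSE, FALSE, TRUE))
    kept <- kept[ord, , drop = FALSE]
    first <- !duplicated(kept$patient_id)
    n_dup <- sum(!first)
    kept <- kept[first, , drop = FALSE]
    kept <- kept[order(kept$patient_id), , drop = FALSE]
    rownames(kept) <- NULL
  }
  report <- structure(class = "curation_report", list(
    n_input = n_input,
    n_excluded_missing = n_missing,
    n_excluded_duplicate_admissions = n_dup,
    n_included = nrow(kept),
    unmapped_terms = unmapped %||%
      data.frame(raw_term = character(0), count = numeric(0))
  ))
  list(records = kept, report = report)
}

#' @export
print.curation_report <- function(x, ...) {
  cat("Curation report\n")
  cat(sprintf("  records in:            %d\n", x$n_input))
  cat(sprintf("  excluded (incomplete): %d\n", x$n_excluded_missing))
  cat(sprintf("  excluded (duplicate):  %d\n",
              x$n_excluded_duplicate_admissions))
  cat(sprintf("  included:              %d\n", x$n_included))
  if (nrow(x$unmapped_terms) > 0) {
    cat(sprintf("  unmapped raw terms:    %d\n", nrow(x$unmapped_terms)))
  }
  invisible(x)
}

#' Write a curation report as JSON
#'
#' @param report A `curation_report` from [apply_inclusion_exclusion()] or
#'   [curate()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curation_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Curate a raw cohort end to end
#'
#' Convenience composition: [normalize_terms()] then
#' [apply_inclusion_exclusion()], mirroring the preprocessing order of an
#' EMR pipeline (standardize the vocabulary first, then filter admissions).
#'
#' @inheritParams normalize_terms
#' @return A list with `records` (curated cohort) and `report`
#'   (`curation_report`).
#' @export
curate <- function(records, dictionary,
                   policy = c("drop_unknown", "strict")) {
  policy <- match.arg(policy)
  norm <- normalize_terms(records, dictionary, policy)
  apply_inclusion_exclusion(norm$records, unmapped = norm$unmapped)
}
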