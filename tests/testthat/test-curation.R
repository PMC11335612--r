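# Curation: normalization, ICD rollup, completeness, inclusion/exclusion.

dict <- data.frame(
  raw_term = c("stomach fullness", "gastric distension variant a",
               "gastric distension variant b", "insomnia",
               "poor appetite", "thready pulse", "dark red tongue",
               "liver-stomach disharmony", "chronic gastritis",
               "smilax glabra"),
  canonical_term = c("stomach fullness", "gastric distension",
                     "gastric distension", "insomnia", "poor appetite",
                     "thready pulse", "dark red tongue",
                     "liver-stomach disharmony", "chronic gastritis",
                     "smilax glabra"),
  feature_class = c("symptom", "symptom", "symptom", "symptom", "symptom",
                    "pulse", "tongue", "diagnosis", "diagnosis", "herb"),
  stringsAsFactors = FALSE
)

test_that("normalize_terms maps synonyms onto one canonical set", {
  r <- rec("p1", main = c("gastric distension variant a",
                          "gastric distension variant b"),
           general = "insomnia", dx = "liver-stomach disharmony")
  out <- normalize_terms(r, dict)
  expect_identical(out$records$main_symptoms[[1]], "gastric distension")
  expect_identical(out$records$general_symptoms[[1]], "insomnia")
  expect_equal(nrow(out$unmapped), 0)
})

test_that("unmapped terms: dropped and logged, or a strict error", {
  r <- rec("p1", main = c("insomnia", "xyzzy"))
  out <- normalize_terms(r, dict, policy = "drop_unknown")
  expect_identical(out$records$main_symptoms[[1]], "insomnia")
  expect_identical(out$unmapped$raw_term, "xyzzy")
  expect_identical(out$unmapped$count, 1)
  expect_error(normalize_terms(r, dict, policy = "strict"),
               class = "psn_normalization_error")
  expect_error(normalize_terms(r, dict, policy = "strict"),
               regexp = "xyzzy")
})

test_that("a term of the wrong feature class is a classification error", {
  r <- rec("p1", main = "smilax glabra")  # a herb in a symptom field
  expect_error(normalize_terms(r, dict), class = "psn_classification_error")
})

test_that("normalization is idempotent on canonical records", {
  r <- rec("p1", main = c("gastric distension variant a", "insomnia"),
           general = "poor appetite", tongue = "dark red tongue",
           pulse = "thready pulse", dx = "liver-stomach disharmony",
           herbs = "smilax glabra", discharge = "insomnia")
  once <- normalize_terms(r, dict, policy = "strict")$records
  twice <- normalize_terms(once, dict, policy = "strict")$records
  for (f in psnstrat:::COHORT_LIST_FIELDS) {
    expect_identical(twice[[f]], once[[f]], label = f)
  }
})

test_that("rollup_icd truncates to one post-decimal character", {
  expect_setequal(rollup_icd(c("I50.903", "I50.905")), "I50.9")
  expect_identical(rollup_icd("K29.400"), "K29.4")
  expect_identical(rollup_icd("K29"), "K29")
  expect_setequal(rollup_icd(c("K29.400", "K29.5", "I50.903")),
                  c("K29.4", "K29.5", "I50.9"))
})

test_that("completeness_score counts populated fields out of ten", {
  full <- rec("p1", main = "a", general = "b", tongue = "c", pulse = "d",
              dx = "e", herbs = "f", discharge = "g",
              outcome = "improvement")
  expect_identical(completeness_score(full), 10L)
  empty <- rec("p1", dx = character(0), outcome = "")
  empty$age <- NA_integer_
  empty$sex <- NA_character_
  expect_identical(completeness_score(empty), 0L)
  partial <- rec("p1", main = "a", general = "b", tongue = "c", pulse = "d",
                 dx = "e", herbs = character(0), discharge = NULL,
                 outcome = "improvement")
  expect_identical(completeness_score(partial), 8L)
})

test_that("inclusion/exclusion keeps the most complete admission", {
  high <- rec("p1", aid = "p1-b", main = "a", general = "b", tongue = "c",
              pulse = "d", herbs = "e", discharge = "f")
  low <- rec("p1", aid = "p1-a", main = "a", herbs = character(0),
             discharge = character(0))
  out <- apply_inclusion_exclusion(cohort_of(low, high))
  expect_identical(out$records$admission_id, "p1-b")
  expect_identical(out$report$n_excluded_duplicate_admissions, 1L)
})

test_that("ties break by latest date then greatest admission id", {
  a <- rec("p1", aid = "p1-a", date = "2020-01-01", main = "x")
  b <- rec("p1", aid = "p1-b", date = "2021-06-01", main = "x")
  out <- apply_inclusion_exclusion(cohort_of(a, b))
  expect_identical(out$records$admission_id, "p1-b")
  c1 <- rec("p1", aid = "p1-c1", date = "2021-06-01", main = "x")
  c2 <- rec("p1", aid = "p1-c2", date = "2021-06-01", main = "x")
  out2 <- apply_inclusion_exclusion(cohort_of(c1, c2))
  expect_identical(out2$records$admission_id, "p1-c2")
})

test_that("records without diagnosis or discharge information are excluded", {
  no_discharge <- rec("p1", main = "a", discharge = NULL, outcome = "")
  no_dx <- rec("p2", main = "a", dx = character(0))
  ok <- rec("p3", main = "a")
  out <- apply_inclusion_exclusion(cohort_of(no_discharge, no_dx, ok))
  expect_identical(out$records$patient_id, "p3")
  expect_identical(out$report$n_excluded_missing, 2L)
  # discharge symptoms observed-empty with no outcome still counts missing
  empty_dis <- rec("p4", main = "a", discharge = character(0), outcome = "")
  expect_identical(
    apply_inclusion_exclusion(empty_dis)$report$n_excluded_missing, 1L)
  # but an outcome alone is enough discharge information
  outcome_only <- rec("p5", main = "a", discharge = NULL,
                      outcome = "improvement")
  expect_identical(
    apply_inclusion_exclusion(outcome_only)$report$n_included, 1L)
})

test_that("report counts always sum to n_input and order does not matter", {
  set.seed(42)
  pool <- lapply(1:24, function(i) {
    pid <- sprintf("p%d", sample.int(8, 1))
    r <- rec(pid, aid = sprintf("adm%02d", i),
             date = as.character(as.Date("2019-01-01") + sample.int(900, 1)),
             main = sample(letters[1:6], sample.int(4, 1)),
             dx = if (runif(1) < 0.15) character(0) else "dx",
             discharge = if (runif(1) < 0.15) NULL else "a",
             outcome = sample(c("improvement", ""), 1))
    r
  })
  records <- do.call(rbind, pool)
  out <- apply_inclusion_exclusion(records)
  rep <- out$report
  expect_identical(rep$n_input,
                   rep$n_included + rep$n_excluded_missing +
                     rep$n_excluded_duplicate_admissions)
  shuffled <- records[sample.int(nrow(records)), , drop = FALSE]
  out2 <- apply_inclusion_exclusion(shuffled)
  expect_identical(out2$records$admission_id, out$records$admission_id)
  expect_identical(unclass(out2$report)[1:4], unclass(out$report)[1:4])
  # empty input: zero-count report
  empty <- apply_inclusion_exclusion(records[0, , drop = FALSE])
  expect_identical(empty$report$n_input, 0L)
  expect_identical(empty$report$n_included, 0L)
})

test_that("curate() composes normalization and filtering", {
  rs <- cohort_of(
    rec("p1", main = c("gastric distension variant a", "xyzzy")),
    rec("p2", main = "insomnia", discharge = NULL, outcome = ""),
    rec("p2", aid = "p2-a2", main = "insomnia"),
    rec("p3", main = "poor appetite")
  )
  out <- curate(rs, dict)
  expect_identical(out$report$n_input, 4L)
  expect_identical(out$report$n_included, 3L)
  expect_identical(out$report$n_excluded_missing, 1L)
  expect_true("xyzzy" %in% out$report$unmapped_terms$raw_term)
  expect_true("icd_rollup" %in% names(out$records))
})
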