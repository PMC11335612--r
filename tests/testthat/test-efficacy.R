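# Symptom resolution between admission and discharge; module profiles.

mk_cohort <- function(n, make) do.call(rbind, lapply(seq_len(n), make))

test_that("resolution follows the present-at-admission/absent-at-discharge rule", {
  records <- mk_cohort(6, function(i) {
    rec(sprintf("p%d", i),
        main = c("stomach pain", "insomnia"),
        discharge = "insomnia")  # stomach pain resolved, insomnia not
  })
  part <- as_psn_partition(stats::setNames(rep(1, 6), sprintf("p%d", 1:6)))
  res <- symptom_resolution(records, part, min_support = 5)
  pain <- res[res$symptom == "stomach pain", ]
  ins <- res[res$symptom == "insomnia", ]
  expect_equal(pain$n_admission, 6)
  expect_equal(pain$n_resolved, 6)
  expect_equal(pain$resolution_rate, 1)
  expect_equal(ins$n_resolved, 0)
  expect_equal(ins$resolution_rate, 0)
  # sorted by descending n_resolved
  expect_identical(res$symptom[1], "stomach pain")
})

test_that("observed-empty discharge sets mean complete resolution", {
  records <- mk_cohort(5, function(i) {
    rec(sprintf("p%d", i), main = "a", general = "b",
        discharge = character(0))
  })
  part <- as_psn_partition(stats::setNames(rep(1, 5), sprintf("p%d", 1:5)))
  res <- symptom_resolution(records, part, min_support = 5)
  expect_true(all(res$resolution_rate == 1))
})

test_that("discharge equal to admission gives the all-zero null", {
  records <- mk_cohort(8, function(i) {
    rec(sprintf("p%d", i), main = c("a", "b"), general = "c",
        discharge = c("a", "b", "c"))
  })
  part <- as_psn_partition(stats::setNames(rep(1:2, 4), sprintf("p%d", 1:8)))
  res <- symptom_resolution(records, part, min_support = 1)
  expect_true(all(res$resolution_rate == 0))
})

test_that("missing discharge records leave the denominators", {
  records <- rbind(
    mk_cohort(6, function(i) rec(sprintf("p%d", i), main = "a",
                                 discharge = character(0))),
    rec("p7", main = "a", discharge = NULL, outcome = "improvement")
  )
  part <- as_psn_partition(stats::setNames(rep(1, 7), sprintf("p%d", 1:7)))
  expect_message(res <- symptom_resolution(records, part, min_support = 1),
                 "without a discharge record")
  expect_equal(res$n_admission[res$symptom == "a"], 6)
})

test_that("min_support suppresses rare symptoms", {
  records <- rbind(
    mk_cohort(6, function(i) rec(sprintf("p%d", i), main = "common",
                                 discharge = character(0))),
    rec("p9", main = "rare", discharge = character(0))
  )
  part <- as_psn_partition(stats::setNames(rep(1, 7),
                                           c(sprintf("p%d", 1:6), "p9")))
  res <- symptom_resolution(records, part, min_support = 5)
  expect_identical(res$symptom, "common")
})

test_that("denominators are conserved across modules and label-invariant", {
  gen <- generate_cohort(generator_config(n_patients = 150, seed = 19))
  cur <- curate(gen$records, gen$dictionary, policy = "strict")
  ids <- cur$records$patient_id
  memb <- stats::setNames(rep_len(1:4, length(ids)), ids)
  part <- as_psn_partition(memb)
  res <- symptom_resolution(cur$records, part, min_support = 1)
  # cohort-wide admission counts among patients with discharge data
  has_dis <- !vapply(cur$records$discharge_symptoms,
                     psnstrat:::is_missing_set, logical(1))
  adm <- table(unlist(lapply(which(has_dis), function(i) {
    union(unlist(cur$records$main_symptoms[i]),
          unlist(cur$records$general_symptoms[i]))
  })))
  per_symptom <- tapply(res$n_admission, res$symptom, sum)
  for (s in names(per_symptom)) {
    expect_identical(as.integer(per_symptom[[s]]), as.integer(adm[[s]]),
                     label = s)
  }
  # relabeling modules does not change any rate
  memb2 <- stats::setNames(5 - unname(memb), names(memb))
  res2 <- symptom_resolution(cur$records, as_psn_partition(memb2),
                             min_support = 1)
  key <- function(d) d[order(d$symptom, d$n_admission, d$n_resolved), ]
  expect_equal(key(res2)[c("symptom", "n_admission", "n_resolved")],
               key(res)[c("symptom", "n_admission", "n_resolved")],
               ignore_attr = TRUE)
})

test_that("pooled background resolution matches the generating rate", {
  cfg <- generator_config()
  gen <- generate_cohort(cfg)
  cur <- curate(gen$records, gen$dictionary, policy = "strict")
  ids <- cur$records$patient_id
  part <- as_psn_partition(stats::setNames(rep(1, length(ids)), ids))
  res <- symptom_resolution(cur$records, part, min_support = 1)
  bg <- res[grepl("^bsym\\.", res$symptom), ]
  pooled <- sum(bg$n_resolved) / sum(bg$n_admission)
  se <- sqrt(cfg$resolution_background * (1 - cfg$resolution_background) /
               sum(bg$n_admission))
  expect_lt(abs(pooled - cfg$resolution_background), 3 * se)
})

test_that("module_profile bundles enrichment and resolution per module", {
  gen <- generate_cohort(generator_config(n_patients = 300, seed = 7))
  cur <- curate(gen$records, gen$dictionary, policy = "strict")
  net <- build_psn(cur$records)
  part <- louvain(net, seed = 7)
  big <- module_size_table(part)$module[1]
  prof <- module_profile(cur$records, part, big, top_k = 5)
  expect_identical(prof$module, big)
  expect_identical(sort(names(prof$enriched)),
                   sort(psnstrat:::FEATURE_CLASSES))
  expect_lte(nrow(prof$enriched$symptom), 5)
  expect_true(all(prof$resolution$module == big))
  expect_error(module_profile(cur$records, part, 9999),
               class = "psn_lookup_error")
  # empty-section contract: classes with no significant feature stay present
  expect_true(is.data.frame(prof$enriched$tongue))
  f <- tempfile(fileext = ".json")
  write_module_profile(prof, f)
  expect_true(jsonlite::validate(readLines(f, warn = FALSE)))
})
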