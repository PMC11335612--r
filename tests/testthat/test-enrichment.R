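# Relative risk and chi-square against closed-form oracles; enrich()
# composition, conservation and degenerate contracts.

test_that("relative_risk reproduces hand-computed worked examples", {
  expect_equal(relative_risk(10, 20, 30, 100), 2.0)
  expect_equal(relative_risk(0, 20, 30, 100), 0.0)
  expect_equal(relative_risk(5, 10, 50, 100), 1.0)  # equal prevalence
  expect_identical(relative_risk(4, 10, 4, 100), Inf)  # module-exclusive
  expect_error(relative_risk(0, 0, 10, 100), class = "psn_undefined_rr")
  expect_error(relative_risk(5, 100, 10, 100), class = "psn_undefined_rr")
})

test_that("chi_square reproduces the worked 2x2 example", {
  # table [[10,10],[20,60]] from (C_ij=10, C_i=20, C_j=30, N=100);
  # expected values frozen from two independent oracles (the closed-form
  # identity and stats::chisq.test(correct = FALSE)): 100*400^2/(20*80*30*70)
  res <- chi_square(10, 20, 30, 100)
  expect_equal(res$chi2, chi2_closed_form(10, 20, 30, 100),
               tolerance = 1e-12)
  expect_equal(res$chi2, 4.761905, tolerance = 1e-6)
  expect_equal(res$p_value, 0.02909633, tolerance = 1e-6)
  # perfectly proportional table: zero statistic, p = 1
  res0 <- chi_square(5, 10, 50, 100)
  expect_equal(res0$chi2, 0)
  expect_equal(res0$p_value, 1)
})

test_that("chi_square errors on degenerate (zero-marginal) tables", {
  expect_error(chi_square(0, 20, 0, 100), class = "psn_degenerate_table")
  expect_error(chi_square(20, 20, 100, 100), class = "psn_degenerate_table")
})

test_that("rr and chi2 match independent oracles on randomized tables", {
  set.seed(101)
  n_checked <- 0
  while (n_checked < 1000) {
    n <- sample(20:500, 1)
    c_i <- sample(1:(n - 1), 1)
    c_j <- sample(1:(n - 1), 1)
    lo <- max(0, c_i + c_j - n); hi <- min(c_i, c_j)
    c_ij <- if (lo == hi) lo else sample(lo:hi, 1)
    if (c_j == 0 || c_j == n) next
    # oracle 1: direct probability ratio
    rr_oracle <- (c_ij / c_i) / ((c_j - c_ij) / (n - c_i))
    if (is.finite(rr_oracle)) {
      expect_equal(relative_risk(c_ij, c_i, c_j, n), rr_oracle,
                   tolerance = 1e-9)
    }
    # oracle 2: closed-form 2x2 identity N(ad-bc)^2 / marginals
    expect_equal(chi_square(c_ij, c_i, c_j, n)$chi2,
                 chi2_closed_form(c_ij, c_i, c_j, n), tolerance = 1e-9)
    n_checked <- n_checked + 1
  }
})

test_that("enrich composes counts, rr and p per (module, feature)", {
  # module A: 20 patients, 10 with "target"; module B: 80 patients, 20 with
  # "target" -> the first chi-square worked example for module A
  rows <- lapply(1:100, function(i) {
    has <- (i <= 10) || (i > 20 && i <= 40)
    rec(sprintf("p%03d", i),
        main = if (has) c("target", "base") else "base",
        general = "g")
  })
  records <- do.call(rbind, rows)
  memb <- stats::setNames(ifelse(seq_len(100) <= 20, "A", "B"),
                          sprintf("p%03d", 1:100))
  part <- as_psn_partition(memb)
  res <- enrich(records, part, "symptom")
  row <- res[res$feature == "target" & res$C_i == 20, ]
  expect_equal(row$C_ij, 10)
  expect_equal(row$C_j, 30)
  expect_equal(row$N, 100)
  expect_equal(row$rr, 2.0)
  expect_equal(row$p_value, 0.02909633, tolerance = 1e-6)
  expect_true(row$significant)
  # conservation: per feature, module counts sum to the cohort count
  for (f in unique(res$feature)) {
    sub <- res[res$feature == f, ]
    expect_identical(sum(sub$C_ij), sub$C_j[1], label = f)
  }
  # sorted within module by descending rr
  for (m in unique(res$module)) {
    expect_false(is.unsorted(rev(res$rr[res$module == m])))
  }
})

test_that("a feature present in every patient has rr 1, never significant", {
  rows <- lapply(1:40, function(i) {
    rec(sprintf("p%02d", i), main = c("ubiquitous",
                                      if (i %% 2) "odd" else "even"))
  })
  records <- do.call(rbind, rows)
  memb <- stats::setNames(rep(c("A", "B"), each = 20), sprintf("p%02d", 1:40))
  res <- enrich(records, as_psn_partition(memb), "symptom")
  ubi <- res[res$feature == "ubiquitous", ]
  expect_equal(nrow(ubi), 2)
  expect_true(all(ubi$rr == 1))
  expect_false(any(ubi$significant))
})

test_that("significance needs strict rr > 1 and p below alpha", {
  rows <- lapply(1:100, function(i) {
    rec(sprintf("p%03d", i),
        main = if (i <= 50) "balanced" else "other")
  })
  records <- do.call(rbind, rows)
  # "balanced" at identical prevalence in both modules: rr = 1 exactly
  memb <- stats::setNames(rep(c("A", "B"), 50), sprintf("p%03d", 1:100))
  res <- enrich(records, as_psn_partition(memb), "symptom")
  bal <- res[res$feature == "balanced", ]
  expect_true(all(bal$rr == 1))
  expect_false(any(bal$significant))
})

test_that("infinite rr serializes as the string inf", {
  rows <- lapply(1:30, function(i) {
    rec(sprintf("p%02d", i), main = if (i <= 5) "exclusive" else "common")
  })
  records <- do.call(rbind, rows)
  memb <- stats::setNames(rep(c("A", "B"), c(10, 20)), sprintf("p%02d", 1:30))
  res <- enrich(records, as_psn_partition(memb), "symptom")
  expect_true(any(is.infinite(res$rr)))
  f <- tempfile(fileext = ".csv")
  write_enrichment(res, f)
  back <- utils::read.csv(f, colClasses = "character")
  expect_true("inf" %in% back$rr)
})

test_that("an absent feature class yields an empty table with a warning", {
  records <- cohort_of(rec("p1", main = "a"), rec("p2", main = "a"))
  part <- as_psn_partition(stats::setNames(c(1, 2), c("p1", "p2")))
  expect_warning(res <- enrich(records, part, "herb"), "no herb features")
  expect_identical(nrow(res), 0L)
})
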