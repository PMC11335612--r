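# Module characterization by relative-risk enrichment with chi-square
# screening.
#
# For module i and feature j over the networked cohort of size N:
#   C_ij = patients in module i with feature j
#   C_i  = patients in module i
#   C_j  = patients with feature j anywhere in the network
# RR = (C_ij / C_i) / ((C_j - C_ij) / (N - C_i)): prevalence inside the
# module over prevalence outside it.

#' Relative risk of a feature in a module
#'
#' Ratio of the feature's prevalence inside the module (exposed group) to
#' its prevalence among all other networked patients (non-exposed group).
#' Returns `Inf` when the feature occurs only inside the module
#' (`C_j == C_ij > 0`) and 0 when it never occurs inside (`C_ij == 0`,
#' `C_j > 0`).
#'
#' @param c_ij Patients in the module with the feature.
#' @param c_i Patients in the module (> 0).
#' @param c_j Patients with the feature in the whole network.
#' @param n Networked patients (> `c_i`).
#' @return A nonnegative number, possibly `Inf`.
#' @examples
#' relative_risk(10, 20, 30, 100)  # 2
#' @export
relative_risk <- function(c_ij, c_i, c_j, n) {
  if (c_i <= 0 || n <= c_i) {
    stop_psn("psn_undefined_rr",
             "relative risk undefined: need 0 < C_i < N (C_i=%s, N=%s)",
             c_i, n)
  }
  if (c_ij > min(c_i, c_j) || c_ij < 0) {
    stop_psn("psn_undefined_rr", "inconsistent contingency counts")
  }
  risk_in <- c_ij / c_i
  out_num <- c_j - c_ij
  if (out_num == 0) {
    if (c_ij == 0) return(NaN)  # feature absent everywhere
    return(Inf)
  }
  risk_in / (out_num / (n - c_i))
}

#' Pearson chi-square test on module-by-feature counts
#'
#' The 2x2 table is `[[C_ij, C_i - C_ij], [C_j - C_ij, N - C_i - C_j +
#' C_ij]]` (module membership x feature presence). Pearson statistic with 1
#' degree of freedom, no continuity correction; p-value from the chi-square
#' survival function. A zero marginal makes the table degenerate and is an
#' error (callers skip such features).
#'
#' @inheritParams relative_risk
#' @return List with `chi2` and `p_value`.
#' @export
chi_square <- function(c_ij, c_i, c_j, n) {
  obs <- matrix(c(c_ij, c_j - c_ij,
                  c_i - c_ij, n - c_i - c_j + c_ij), 2, 2)
  if (any(obs < 0)) stop_psn("psn_degenerate_table",
                             "negative cell in 2x2 table")
  rs <- rowSums(obs)
  cs <- colSums(obs)
  if (any(rs == 0) || any(cs == 0)) {
    stop_psn("psn_degenerate_table",
             "degenerate 2x2 table (zero marginal)")
  }
  expected <- outer(rs, cs) / n
  chi2 <- sum((obs - expected)^2 / expected)
  list(chi2 = chi2, p_value = stats::pchisq(chi2, df = 1,
                                            lower.tail = FALSE))
}

# Which record fields feed each enrichment feature class.
feature_terms <- function(records, feature_class) {
  switch(feature_class,
    symptom = mapply(function(a, b) {
      union(as_term_set(a) %||% character(0),
            as_term_set(b) %||% character(0))
    }, records$main_symptoms, records$general_symptoms, SIMPLIFY = FALSE),
    tongue = lapply(records$tongue_features,
                    function(x) as_term_set(x) %||% character(0)),
    pulse = lapply(records$pulse_features,
                   function(x) as_term_set(x) %||% character(0)),
    diagnosis = mapply(function(a, b) {
      union(as_term_set(a) %||% character(0),
            as_term_set(b) %||% character(0))
    }, records$tcm_diagnoses,
       records$icd_rollup %||% replicate(nrow(records), NULL),
       SIMPLIFY = FALSE),
    herb = lapply(records$herbs, function(x) as_term_set(x) %||% character(0)),
    stop_psn("psn_parameter_error", "unknown feature class: %s",
             feature_class)
  )
}

#' Relative-risk enrichment of features across modules
#'
#' For every (module, feature) pair with at least one carrier in the module
#' (`C_ij > 0`), computes the contingency counts, relative risk and Pearson
#' chi-square p-value over the networked cohort, and flags the pair
#' significant when `RR > 1` and `p < alpha`. Enrichment is computed
#' against the patients in the partition (the network universe), not the
#' full curated cohort. Features spanning the whole cohort or a whole
#' marginal are skipped as degenerate.
#'
#' @param records Curated cohort data frame covering all partition nodes.
#' @param partition A `psn_partition`.
#' @param feature_class One of `"symptom"`, `"tongue"`, `"pulse"`,
#'   `"diagnosis"`, `"herb"`. The symptom class pools main and general
#'   symptoms; the diagnosis class pools TCM diagnoses and rolled-up ICD
#'   codes.
#' @param alpha Significance level (default 0.05, uncorrected).
#' @param p_adjust `"none"` (default) or `"BH"` for Benjamini-Hochberg
#'   across all tested pairs of this class.
#' @return Data frame with one row per tested pair: `module`, `feature`,
#'   `feature_class`, `C_ij`, `C_i`, `C_j`, `N`, `rr`, `chi2`, `p_value`,
#'   `significant`; sorted by module, then descending RR.
#' @export
enrich <- function(records, partition, feature_class, alpha = 0.05,
                   p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(inherits(partition, "psn_partition"))
  feature_class <- match.arg(feature_class, FEATURE_CLASSES)
  nodes <- names(partition$membership)
  idx <- match(nodes, records$patient_id)
  if (anyNA(idx)) {
    stop_psn("psn_coverage_error",
             "records missing for %d partition nodes", sum(is.na(idx)))
  }
  recs <- records[idx, , drop = FALSE]
  terms <- feature_terms(recs, feature_class)
  n_total <- length(nodes)
  all_terms <- unlist(terms)
  if (length(all_terms) == 0) {
    warning(sprintf("no %s features present in the cohort", feature_class))
    return(empty_enrichment())
  }
  carrier <- data.frame(
    patient = rep(seq_along(terms), lengths(terms)),
    term = all_terms, stringsAsFactors = FALSE
  )
  c_j <- table(carrier$term)
  membership <- partition$membership[nodes]
  c_i <- table(membership)
  rows <- list()
  for (mod in as.integer(names(c_i))) {
    in_mod <- membership == mod
    sub <- carrier[in_mod[carrier$patient], , drop = FALSE]
    c_ij <- table(sub$term)
    ci <- as.integer(c_i[[as.character(mod)]])
    if (ci == 0 || ci >= n_total) next  # degenerate module marginal
    for (term in names(c_ij)) {
      cij <- as.integer(c_ij[[term]])
      cj <- as.integer(c_j[[term]])
      if (cj == n_total) {
        # feature in every patient: rr = 1 by definition, never significant
        rows[[length(rows) + 1]] <- data.frame(
          module = mod, feature = term, feature_class = feature_class,
          C_ij = cij, C_i = ci, C_j = cj, N = n_total,
          rr = 1, chi2 = 0, p_value = 1, significant = FALSE,
          stringsAsFactors = FALSE)
        next
      }
      rr <- relative_risk(cij, ci, cj, n_total)
      cs <- chi_square(cij, ci, cj, n_total)
      rows[[length(rows) + 1]] <- data.frame(
        module = mod, feature = term, feature_class = feature_class,
        C_ij = cij, C_i = ci, C_j = cj, N = n_total,
        rr = rr, chi2 = cs$chi2, p_value = cs$p_value, significant = NA,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty_enrichment())
  out <- do.call(rbind, rows)
  if (p_adjust == "BH") {
    out$p_value <- stats::p.adjust(out$p_value, method = "BH")
  }
  out$significant <- out$rr > 1 & out$p_value < alpha
  out <- out[order(out$module, -out$rr, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_enrichment <- function() {
  data.frame(module = integer(0), feature = character(0),
             feature_class = character(0), C_ij = integer(0),
             C_i = integer(0), C_j = integer(0), N = integer(0),
             rr = numeric(0), chi2 = numeric(0), p_value = numeric(0),
             significant = logical(0), stringsAsFactors = FALSE)
}

#' Write an enrichment table as CSV
#'
#' Infinite relative risks are serialized as the string `"inf"`.
#'
#' @param results Data frame from [enrich()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(results, path) {
  out <- results
  out$rr <- ifelse(is.infinite(out$rr), "inf", format(out$rr, digits = 15))
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
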