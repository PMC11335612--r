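# Admission-vs-discharge symptom comparison per module, and the combined
# per-module profile (enriched phenotypes + herbs + resolution ranking).

#' Per-module symptom resolution between admission and discharge
#'
#' A symptom is *resolved* for a patient when it is present in the
#' admission record (main or general symptoms) and absent from the
#' discharge symptom set of the same hospitalization. For every (module,
#' symptom) pair with at least `min_support` carriers at admission, reports
#' the number admitted with it, the number resolved, and the resolution
#' rate. Patients whose discharge symptom set is missing (never filed, as
#' opposed to observed empty) are excluded from all denominators.
#'
#' @param records Curated cohort data frame covering the partition nodes.
#' @param partition A `psn_partition`.
#' @param min_support Minimum admission carriers per (module, symptom) row
#'   (default 5; rarer symptoms give unstable rates).
#' @return Data frame `module`, `symptom`, `n_admission`, `n_resolved`,
#'   `resolution_rate`, sorted within module by descending `n_resolved`,
#'   then descending rate, then symptom.
#' @export
symptom_resolution <- function(records, partition, min_support = 5) {
  stopifnot(inherits(partition, "psn_partition"))
  nodes <- names(partition$membership)
  idx <- match(nodes, records$patient_id)
  if (anyNA(idx)) {
    stop_psn("psn_coverage_error",
             "records missing for %d partition nodes", sum(is.na(idx)))
  }
  recs <- records[idx, , drop = FALSE]
  has_discharge <- !vapply(recs$discharge_symptoms, is_missing_set,
                           logical(1))
  if (any(!has_discharge)) {
    message(sprintf(
      "symptom_resolution: %d patient(s) without a discharge record excluded",
      sum(!has_discharge)))
  }
  recs <- recs[has_discharge, , drop = FALSE]
  membership <- partition$membership[recs$patient_id]
  admission <- feature_terms(recs, "symptom")
  rows <- list()
  for (mod in sort(unique(membership))) {
    in_mod <- which(membership == mod)
    adm <- admission[in_mod]
    dis <- recs$discharge_symptoms[in_mod]
    long <- data.frame(
      patient = rep(seq_along(adm), lengths(adm)),
      symptom = unlist(adm), stringsAsFactors = FALSE
    )
    if (nrow(long) == 0) next
    long$resolved <- mapply(function(p, s) !(s %in% dis[[p]]),
                            long$patient, long$symptom)
    n_adm <- table(long$symptom)
    n_res <- tapply(long$resolved, long$symptom, sum)
    keep <- names(n_adm)[n_adm >= min_support]
    for (s in keep) {
      rows[[length(rows) + 1]] <- data.frame(
        module = mod, symptom = s,
        n_admission = as.integer(n_adm[[s]]),
        n_resolved = as.integer(n_res[[s]]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(module = integer(0), symptom = character(0),
                      n_admission = integer(0), n_resolved = integer(0),
                      resolution_rate = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out$resolution_rate <- out$n_resolved / out$n_admission
  out <- out[order(out$module, -out$n_resolved, -out$resolution_rate,
                   out$symptom), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Structured profile of one patient module
#'
#' Bundles the module's top significant features from all five enrichment
#' classes (symptoms, tongue, pulse, diagnoses, herbs) with its symptom
#' resolution ranking into one JSON-serializable report — the per-subgroup
#' phenotype/treatment characterization. Herb-symptom association is
#' reported as module-level co-occurrence only; no causal claim is made or
#' modeled.
#'
#' @param records Curated cohort data frame.
#' @param partition A `psn_partition`.
#' @param module_id Module to profile.
#' @param alpha Significance level for enrichment.
#' @param top_k Features listed per class (default 10, ranked by RR) and
#'   resolution rows kept.
#' @param min_support Passed to [symptom_resolution()].
#' @return A list with `module`, `n_patients`, one ranked data frame per
#'   feature class under `enriched`, and `resolution`.
#' @export
module_profile <- function(records, partition, module_id, alpha = 0.05,
                           top_k = 10, min_support = 5) {
  stopifnot(inherits(partition, "psn_partition"))
  if (!(module_id %in% partition$membership)) {
    stop_psn("psn_lookup_error", "unknown module id: %s", module_id)
  }
  enriched <- lapply(stats::setNames(FEATURE_CLASSES, FEATURE_CLASSES),
                     function(cl) {
    res <- suppressWarnings(enrich(records, partition, cl, alpha = alpha))
    res <- res[res$module == module_id & res$significant, , drop = FALSE]
    utils::head(res[order(-res$rr, res$p_value, res$feature), , drop = FALSE],
                top_k)
  })
  resolution <- symptom_resolution(records, partition,
                                   min_support = min_support)
  resolution <- utils::head(
    resolution[resolution$module == module_id, , drop = FALSE], top_k)
  list(
    module = module_id,
    n_patients = sum(partition$membership == module_id),
    enriched = enriched,
    resolution = resolution
  )
}

#' Write a module profile as JSON
#'
#' @param profile List from [module_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_module_profile <- function(profile, path) {
  ser <- profile
  ser$enriched <- lapply(ser$enriched, function(d) {
    d$rr <- ifelse(is.infinite(d$rr), "inf", d$rr)
    d
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
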