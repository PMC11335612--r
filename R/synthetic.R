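# Synthetic EMR cohorts with planted subgroup structure.
#
# The generator emulates the *structure* of a symptom-coded inpatient EMR
# extract: K latent subgroups with disjoint signature main/general symptom
# sets, subgroup-linked herb signatures, per-symptom treatment-response
# probabilities, synonym noise resolvable through the emitted dictionary,
# duplicate admissions and incomplete records. It makes no attempt to
# reproduce any real cohort's symptom marginals; demographics default to a
# published-style elderly gastritis cohort (age 59.27 +/- 11.44, 52.6%
# male) so summary tables look comparable.

#' Configuration for the synthetic cohort generator
#'
#' @param n_patients Cohort size (default 1000).
#' @param n_subgroups Number of planted subgroups K (default 3).
#' @param mixing_proportions Simplex vector of length K (default uniform).
#' @param m_signature_main Signature main symptoms per subgroup (default 5).
#' @param m_signature_general Signature general symptoms per subgroup
#'   (default 8).
#' @param n_background Background symptom pool size shared by the main and
#'   general channels (default 40).
#' @param p_signature Probability each signature symptom appears in a
#'   subgroup member's record (default 0.85).
#' @param p_background Probability each background term appears (default
#'   0.05); also used for background herbs.
#' @param m_herb_signature Signature herbs per subgroup (default 5).
#' @param p_herb_signature Probability each signature herb is prescribed to
#'   a subgroup member (default 0.9).
#' @param n_background_herbs Background herb pool size (default 20).
#' @param resolution_given_signature_herb Probability a signature symptom
#'   resolves by discharge when the patient received at least one signature
#'   herb of their subgroup (default 0.9).
#' @param resolution_background Resolution probability for all other
#'   admission symptoms (default 0.4).
#' @param synonym_rate Probability an emitted term is written as its raw
#'   synonym instead of the canonical form (default 0.1).
#' @param duplicate_admission_rate Probability a patient has an extra,
#'   less complete admission record (default 0.05).
#' @param missingness_rate Probability a patient's primary record lacks
#'   discharge information (default 0.03).
#' @param age_mean,age_sd Age distribution in years (defaults 59.27,
#'   11.44; truncated to 18..99).
#' @param p_male Probability of male sex (default 0.526).
#' @param seed Integer seed (default 7).
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(n_patients = 1000,
                             n_subgroups = 3,
                             mixing_proportions = NULL,
                             m_signature_main = 5,
                             m_signature_general = 8,
                             n_background = 40,
                             p_signature = 0.85,
                             p_background = 0.05,
                             m_herb_signature = 5,
                             p_herb_signature = 0.9,
                             n_background_herbs = 20,
                             resolution_given_signature_herb = 0.9,
                             resolution_background = 0.4,
                             synonym_rate = 0.1,
                             duplicate_admission_rate = 0.05,
                             missingness_rate = 0.03,
                             age_mean = 59.27,
                             age_sd = 11.44,
                             p_male = 0.526,
                             seed = 7) {
  k <- as.integer(n_subgroups)
  mixing_proportions <- mixing_proportions %||% rep(1 / k, k)
  cfg <- structure(class = "generator_config", list(
    n_patients = as.integer(n_patients), n_subgroups = k,
    mixing_proportions = mixing_proportions,
    m_signature_main = as.integer(m_signature_main),
    m_signature_general = as.integer(m_signature_general),
    n_background = as.integer(n_background),
    p_signature = p_signature, p_background = p_background,
    m_herb_signature = as.integer(m_herb_signature),
    p_herb_signature = p_herb_signature,
    n_background_herbs = as.integer(n_background_herbs),
    resolution_given_signature_herb = resolution_given_signature_herb,
    resolution_background = resolution_background,
    synonym_rate = synonym_rate,
    duplicate_admission_rate = duplicate_admission_rate,
    missingness_rate = missingness_rate,
    age_mean = age_mean, age_sd = age_sd, p_male = p_male,
    seed = as.integer(seed)
  ))
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  probs <- c(cfg$p_signature, cfg$p_background, cfg$p_herb_signature,
             cfg$resolution_given_signature_herb, cfg$resolution_background,
             cfg$synonym_rate, cfg$duplicate_admission_rate,
             cfg$missingness_rate, cfg$p_male)
  if (any(probs < 0 | probs > 1)) {
    stop_psn("psn_config_error", "all probabilities must lie in [0, 1]")
  }
  if (cfg$n_patients < 1 || cfg$n_subgroups < 1) {
    stop_psn("psn_config_error", "n_patients and n_subgroups must be >= 1")
  }
  if (length(cfg$mixing_proportions) != cfg$n_subgroups ||
      any(cfg$mixing_proportions < 0) ||
      abs(sum(cfg$mixing_proportions) - 1) > 1e-8) {
    stop_psn("psn_config_error",
             "mixing_proportions must be a length-K simplex vector")
  }
  if (cfg$age_sd < 0) stop_psn("psn_config_error", "age_sd must be >= 0")
  cfg
}

# Vocabulary: canonical terms per channel, pairwise-disjoint subgroup
# signatures by construction.
synthetic_vocabulary <- function(cfg) {
  k <- cfg$n_subgroups
  list(
    main_sig = lapply(seq_len(k), function(s)
      sprintf("msym.s%d.%02d", s, seq_len(cfg$m_signature_main))),
    general_sig = lapply(seq_len(k), function(s)
      sprintf("gsym.s%d.%02d", s, seq_len(cfg$m_signature_general))),
    background = sprintf("bsym.%02d", seq_len(cfg$n_background)),
    herb_sig = lapply(seq_len(k), function(s)
      sprintf("herb.s%d.%02d", s, seq_len(cfg$m_herb_signature))),
    herb_bg = sprintf("bherb.%02d", seq_len(cfg$n_background_herbs)),
    tongue_sig = sprintf("tongue.s%d", seq_len(k)),
    pulse_sig = sprintf("pulse.s%d", seq_len(k)),
    dx_sig = sprintf("syndrome.s%d", seq_len(k)),
    tongue_common = "tongue.common",
    pulse_common = "pulse.common",
    dx_common = "dx.cag"
  )
}

synthetic_dictionary <- function(vocab) {
  canon <- c(unlist(vocab$main_sig), unlist(vocab$general_sig),
             vocab$background, unlist(vocab$herb_sig), vocab$herb_bg,
             vocab$tongue_sig, vocab$tongue_common,
             vocab$pulse_sig, vocab$pulse_common,
             vocab$dx_sig, vocab$dx_common)
  cls <- c(
    rep("symptom", length(unlist(vocab$main_sig)) +
          length(unlist(vocab$general_sig)) + length(vocab$background)),
    rep("herb", length(unlist(vocab$herb_sig)) + length(vocab$herb_bg)),
    rep("tongue", length(vocab$tongue_sig) + 1),
    rep("pulse", length(vocab$pulse_sig) + 1),
    rep("diagnosis", length(vocab$dx_sig) + 1)
  )
  # identity rows plus one raw synonym ("<term>::raw") per canonical term
  data.frame(
    raw_term = c(canon, paste0(canon, "::raw")),
    canonical_term = c(canon, canon),
    feature_class = c(cls, cls),
    stringsAsFactors = FALSE
  )
}

draw_terms <- function(pool, p) pool[stats::runif(length(pool)) < p]

apply_synonyms <- function(terms, rate) {
  if (length(terms) == 0) return(terms)
  flip <- stats::runif(length(terms)) < rate
  terms[flip] <- paste0(terms[flip], "::raw")
  terms
}

#' Generate a synthetic EMR cohort with planted subgroups
#'
#' Each patient draws a subgroup from the mixing proportions; signature
#' symptoms/herbs appear with `p_signature`/`p_herb_signature`, background
#' terms with `p_background`. Discharge symptoms are the admission symptoms
#' minus those that resolved: a signature symptom resolves with probability
#' `resolution_given_signature_herb` when the patient received any herb of
#' their subgroup's signature, otherwise everything resolves with
#' `resolution_background`. Raw-term synonyms, duplicate admissions and
#' missing discharge records are then injected at the configured rates.
#' Fully reproducible from `config$seed`.
#'
#' @param config A `generator_config`.
#' @return List with `records` (raw cohort data frame, see
#'   [cohort-format]), `truth` (data frame `patient_id`, `subgroup`), and
#'   `dictionary` (term dictionary resolving every emitted raw term).
#' @export
generate_cohort <- function(config) {
  cfg <- validate_generator_config(config)
  vocab <- synthetic_vocabulary(cfg)
  dictionary <- synthetic_dictionary(vocab)
  n <- cfg$n_patients
  k <- cfg$n_subgroups
  with_seed(cfg$seed, {
    subgroup <- sample.int(k, n, replace = TRUE,
                           prob = cfg$mixing_proportions)
    pid <- sprintf("P%05d", seq_len(n))
    rows <- vector("list", n)
    extra <- list()
    for (i in seq_len(n)) {
      s <- subgroup[i]
      main <- c(draw_terms(vocab$main_sig[[s]], cfg$p_signature),
                draw_terms(vocab$background, cfg$p_background))
      general <- c(draw_terms(vocab$general_sig[[s]], cfg$p_signature),
                   draw_terms(vocab$background, cfg$p_background))
      herbs <- c(draw_terms(vocab$herb_sig[[s]], cfg$p_herb_signature),
                 draw_terms(vocab$herb_bg, cfg$p_background))
      got_sig_herb <- any(herbs %in% vocab$herb_sig[[s]])
      admission <- unique(c(main, general))
      sig_sym <- c(vocab$main_sig[[s]], vocab$general_sig[[s]])
      p_res <- ifelse(admission %in% sig_sym & got_sig_herb,
                      cfg$resolution_given_signature_herb,
                      cfg$resolution_background)
      resolved <- stats::runif(length(admission)) < p_res
      discharge <- admission[!resolved]
      tongue <- c(draw_terms(vocab$tongue_sig[s], 0.8),
                  draw_terms(vocab$tongue_common, 0.5))
      pulse <- c(draw_terms(vocab$pulse_sig[s], 0.8),
                 draw_terms(vocab$pulse_common, 0.5))
      dx <- c(vocab$dx_common, draw_terms(vocab$dx_sig[s], 0.9))
      outcome <- sample(OUTCOME_LEVELS, 1,
                        prob = c(0.661, 0.329, 0.003, 0.007))
      date <- as.Date("2013-01-01") +
        floor(stats::runif(1, 0, as.numeric(as.Date("2023-12-31") -
                                              as.Date("2013-01-01"))))
      age <- round(stats::rnorm(1, cfg$age_mean, cfg$age_sd))
      age <- max(18, min(99, age))
      sex <- if (stats::runif(1) < cfg$p_male) "male" else "female"
      rec <- list(
        patient_id = pid[i],
        admission_id = paste0(pid[i], "-a1"),
        admission_date = date, age = as.integer(age), sex = sex,
        main_symptoms = apply_synonyms(main, cfg$synonym_rate),
        general_symptoms = apply_synonyms(general, cfg$synonym_rate),
        tongue_features = apply_synonyms(tongue, cfg$synonym_rate),
        pulse_features = apply_synonyms(pulse, cfg$synonym_rate),
        tcm_diagnoses = apply_synonyms(dx, cfg$synonym_rate),
        icd_codes = "K29.400",
        herbs = apply_synonyms(herbs, cfg$synonym_rate),
        discharge_symptoms = apply_synonyms(discharge, cfg$synonym_rate),
        outcome = outcome
      )
      # a duplicate, less complete admission for some patients
      if (stats::runif(1) < cfg$duplicate_admission_rate) {
        dup <- rec
        dup$admission_id <- paste0(pid[i], "-a0")
        dup$admission_date <- date - floor(stats::runif(1, 30, 400))
        dup$herbs <- character(0)
        dup$general_symptoms <- character(0)
        extra[[length(extra) + 1]] <- dup
      }
      # some primary records never get a discharge record filed
      if (stats::runif(1) < cfg$missingness_rate) {
        rec$discharge_symptoms <- NULL
        rec$outcome <- ""
      }
      rows[[i]] <- rec
    }
    all_rows <- c(rows, extra)
    records <- data.frame(
      patient_id = vapply(all_rows, `[[`, character(1), "patient_id"),
      admission_id = vapply(all_rows, `[[`, character(1), "admission_id"),
      admission_date = as.Date(vapply(all_rows, function(r)
        as.character(r$admission_date), character(1))),
      age = vapply(all_rows, `[[`, integer(1), "age"),
      sex = vapply(all_rows, `[[`, character(1), "sex"),
      stringsAsFactors = FALSE
    )
    for (f in COHORT_LIST_FIELDS) {
      records[[f]] <- lapply(all_rows, function(r) r[[f]])
    }
    records$outcome <- vapply(all_rows, `[[`, character(1), "outcome")
    records <- records[COHORT_COLUMNS]
    list(
      records = records,
      truth = data.frame(patient_id = pid, subgroup = subgroup,
                         stringsAsFactors = FALSE),
      dictionary = dictionary
    )
  })
}

#' Write planted truth labels
#'
#' 2-column TSV `patient_id<TAB>subgroup`.
#'
#' @param truth Truth data frame from [generate_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Run the full pipeline on a synthetic cohort and score recovery
#'
#' Generates a cohort, curates it (strict normalization against the
#' emitted dictionary), builds the PSN, partitions it with Louvain, runs
#' symptom and herb enrichment and symptom resolution, and scores how well
#' the planted structure was recovered. Each planted subgroup is mapped to
#' the detected module holding the plurality of its networked members;
#' signature recall and cross-module specificity are assessed over these
#' mapped modules (satellite fragments of the same subgroup are not counted
#' as foreign modules).
#'
#' @param config A `generator_config`.
#' @param main_threshold Main-symptom PSN threshold (default 0.8).
#' @param alpha Enrichment significance level (default 0.05).
#' @param min_support Passed to [symptom_resolution()].
#' @return List of metrics: `ari` (Louvain vs planted labels over networked
#'   patients), `n_nodes`, `n_modules`, `module_map` (subgroup -> module),
#'   `signature_symptom_recall`, `signature_herb_recall`,
#'   `cross_module_false_flags` (signatures significant in another
#'   subgroup's mapped module), `resolution_error_signature`,
#'   `resolution_error_background`, `resolution_error` (combined mean
#'   absolute error against the generating probabilities).
#' @export
recovery_experiment <- function(config, main_threshold = 0.8, alpha = 0.05,
                                min_support = 5) {
  cfg <- validate_generator_config(config)
  gen <- generate_cohort(cfg)
  cur <- curate(gen$records, gen$dictionary, policy = "strict")
  net <- build_psn(cur$records, main_threshold = main_threshold)
  part <- louvain(net, seed = cfg$seed)
  truth <- stats::setNames(gen$truth$subgroup, gen$truth$patient_id)
  nodes <- names(part$membership)
  ari <- adjusted_rand_index(truth[nodes], part$membership[nodes])

  # map each planted subgroup to its plurality module
  vocab <- synthetic_vocabulary(cfg)
  k <- cfg$n_subgroups
  module_map <- vapply(seq_len(k), function(s) {
    members <- nodes[truth[nodes] == s]
    if (length(members) == 0) return(NA_integer_)
    tab <- table(part$membership[members])
    as.integer(names(tab)[which.max(tab)])
  }, integer(1))

  enr_sym <- enrich(cur$records, part, "symptom", alpha = alpha)
  enr_herb <- enrich(cur$records, part, "herb", alpha = alpha)
  sig_hits <- function(enr, signatures) {
    hit_own <- 0L; n_sig <- 0L; false_cross <- 0L
    for (s in seq_len(k)) {
      for (term in signatures[[s]]) {
        n_sig <- n_sig + 1L
        own <- enr[enr$module == module_map[s] & enr$feature == term, ]
        if (nrow(own) > 0 && any(own$significant)) hit_own <- hit_own + 1L
        other <- enr[enr$module %in% module_map[-s] & enr$feature == term &
                       enr$significant, ]
        false_cross <- false_cross + nrow(other)
      }
    }
    list(recall = hit_own / n_sig, false_cross = false_cross)
  }
  sym_sig <- lapply(seq_len(k), function(s)
    c(vocab$main_sig[[s]], vocab$general_sig[[s]]))
  hits_sym <- sig_hits(enr_sym, sym_sig)
  hits_herb <- sig_hits(enr_herb, vocab$herb_sig)

  res <- symptom_resolution(cur$records, part, min_support = min_support)
  sig_err <- c(); bg_err <- c()
  for (s in seq_len(k)) {
    rows <- res[res$module == module_map[s], , drop = FALSE]
    in_sig <- rows$symptom %in% sym_sig[[s]]
    in_bg <- rows$symptom %in% vocab$background
    sig_err <- c(sig_err, abs(rows$resolution_rate[in_sig] -
                                cfg$resolution_given_signature_herb))
    bg_err <- c(bg_err, abs(rows$resolution_rate[in_bg] -
                              cfg$resolution_background))
  }
  list(
    ari = ari,
    n_nodes = length(nodes),
    n_modules = part$n_modules,
    modularity = part$modularity,
    module_map = module_map,
    signature_symptom_recall = hits_sym$recall,
    signature_herb_recall = hits_herb$recall,
    cross_module_false_flags = hits_sym$false_cross + hits_herb$false_cross,
    resolution_error_signature = mean(sig_err),
    resolution_error_background = mean(bg_err),
    resolution_error = mean(c(sig_err, bg_err))
  )
}
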