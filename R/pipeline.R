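# End-to-end orchestration: cohort summary, staged pipeline runner with a
# reproducibility manifest (per-artifact md5 digests, per-stage timings).

AGE_BANDS <- data.frame(
  band = c("<20", "20-39", "40-59", "60-79", ">=80"),
  lo = c(-Inf, 20, 40, 60, 80),
  hi = c(20, 40, 60, 80, Inf)  # half-open [lo, hi)
)

#' Summarize a curated cohort
#'
#' Sex counts with percentages (two decimals), age mean +/- sd, counts per
#' age band (half-open bands `<20`, `20-39`, `40-59`, `60-79`, `>=80`) and
#' outcome tallies. Percentages are always recomputed from the counts.
#'
#' @param records Curated cohort data frame (one row per patient).
#' @return A `cohort_summary` list.
#' @export
summarize_cohort <- function(records) {
  n <- nrow(records)
  if (n == 0) stop_psn("psn_empty_cohort", "cannot summarize an empty cohort")
  sex_n <- c(male = sum(records$sex == "male", na.rm = TRUE),
             female = sum(records$sex == "female", na.rm = TRUE))
  ages <- records$age[!is.na(records$age)]
  band_n <- vapply(seq_len(nrow(AGE_BANDS)), function(i) {
    sum(ages >= AGE_BANDS$lo[i] & ages < AGE_BANDS$hi[i])
  }, integer(1))
  names(band_n) <- AGE_BANDS$band
  outcome_n <- table(factor(records$outcome,
                            levels = c(OUTCOME_LEVELS, "")))
  structure(class = "cohort_summary", list(
    n = n,
    sex = data.frame(sex = names(sex_n), n = as.integer(sex_n),
                     pct = round(100 * as.integer(sex_n) / n, 2)),
    age_mean = mean(ages),
    age_sd = stats::sd(ages),
    age_bands = data.frame(band = names(band_n), n = as.integer(band_n),
                           pct = round(100 * as.integer(band_n) /
                                         length(ages), 2)),
    outcomes = data.frame(outcome = names(outcome_n),
                          n = as.integer(outcome_n))
  ))
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d patients\n", x$n))
  cat(sprintf("  age: %.2f +/- %.2f years\n", x$age_mean, x$age_sd))
  for (i in seq_len(nrow(x$sex))) {
    cat(sprintf("  %s: %d (%.2f%%)\n", x$sex$sex[i], x$sex$n[i],
                x$sex$pct[i]))
  }
  invisible(x)
}

default_pipeline_config <- function() {
  list(
    input = list(records = NULL, dictionary = NULL, synthetic = NULL),
    curation = list(policy = "drop_unknown"),
    psn = list(main_threshold = 0.8),
    communities = list(resolution = 1.0, tolerance = 1e-7,
                       bigclam = list(enabled = FALSE, n_communities = 10)),
    enrichment = list(alpha = 0.05, p_adjust = "none"),
    efficacy = list(min_support = 5),
    profile = list(top_k_modules = 3, top_k_features = 10),
    seed = 7
  )
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]])) {
      base[[k]] <- merge_config(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Load a pipeline configuration
#'
#' Reads YAML (if the yaml package is installed) or JSON and fills unset
#' entries with package defaults. `input$synthetic` may hold
#' [generator_config()] arguments to simulate the inputs instead of reading
#' files.
#'
#' @param path Config file path, or `NULL` for pure defaults.
#' @return A config list.
#' @export
load_pipeline_config <- function(path = NULL) {
  cfg <- default_pipeline_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) {
    stop_psn("psn_config_error", "config file not found: %s", path)
  }
  user <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_psn("psn_config_error",
               "YAML config requires the yaml package; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  }
  merge_config(cfg, user)
}

#' Run the stratification pipeline end to end
#'
#' Stages: curate, psn, communities, enrichment (all five feature classes),
#' efficacy, profiles. Inputs come from `config$input` — either file paths
#' (`records`, `dictionary`) or a `synthetic` block of [generator_config()]
#' arguments. All artifacts plus a run manifest (config snapshot, seed,
#' md5 digest and byte size per artifact, stage timings, package version)
#' are written under `out_dir`. On a stage failure, artifacts written so
#' far are moved under `out_dir/failed/` and the error (classed
#' `psn_stage_failure`) names the stage.
#'
#' @param config Config list ([load_pipeline_config()]) or a path to one.
#' @param out_dir Output directory (created if absent).
#' @param seed Optional integer overriding `config$seed`.
#' @return The manifest list, invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- load_pipeline_config(config)
  config <- merge_config(default_pipeline_config(), config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  stages <- list()
  state <- new.env(parent = emptyenv())

  emit <- function(name) artifacts <<- c(artifacts, name)
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    ok <- tryCatch({ fun(); TRUE }, error = function(e) e)
    elapsed <- proc.time()[["elapsed"]] - t0
    if (!isTRUE(ok)) {
      failed_dir <- file.path(out_dir, "failed")
      dir.create(failed_dir, showWarnings = FALSE)
      for (a in artifacts) {
        from <- file.path(out_dir, a)
        if (file.exists(from)) file.rename(from, file.path(failed_dir, a))
      }
      stop_psn("psn_stage_failure", "pipeline failed at stage '%s': %s",
               name, conditionMessage(ok))
    }
    stages[[length(stages) + 1]] <<- list(stage = name,
                                          seconds = round(elapsed, 3))
  }

  run_stage("curate", function() {
    if (!is.null(config$input$synthetic)) {
      gcfg <- do.call(generator_config,
                      c(config$input$synthetic,
                        list(seed = config$seed)))
      gen <- generate_cohort(gcfg)
      write_records(gen$records, file.path(out_dir, "records.csv"))
      write_term_dictionary(gen$dictionary,
                            file.path(out_dir, "dictionary.tsv"))
      write_truth(gen$truth, file.path(out_dir, "truth.tsv"))
      emit("records.csv"); emit("dictionary.tsv"); emit("truth.tsv")
      raw <- gen$records
      dict <- gen$dictionary
    } else {
      if (is.null(config$input$records) ||
          !file.exists(config$input$records)) {
        stop_psn("psn_io_error", "records file not found: %s",
                 config$input$records %||% "<unset>")
      }
      raw <- read_records(config$input$records)
      dict <- read_term_dictionary(config$input$dictionary %||% "")
    }
    cur <- curate(raw, dict, policy = config$curation$policy)
    state$records <- cur$records
    write_records(cur$records, file.path(out_dir, "curated.csv"))
    write_curation_report(cur$report, file.path(out_dir,
                                                "curation_report.json"))
    emit("curated.csv"); emit("curation_report.json")
    summary <- summarize_cohort(cur$records)
    jsonlite::write_json(unclass(summary),
                         file.path(out_dir, "cohort_summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    emit("cohort_summary.json")
  })

  run_stage("psn", function() {
    net <- build_psn(state$records,
                     main_threshold = config$psn$main_threshold)
    state$network <- net
    write_psn_edgelist(net, file.path(out_dir, "psn_edgelist.txt"))
    write_psn_graphml(net, file.path(out_dir, "psn.graphml"))
    emit("psn_edgelist.txt"); emit("psn.graphml")
  })

  run_stage("communities", function() {
    part <- louvain(state$network, seed = config$seed,
                    tolerance = config$communities$tolerance,
                    resolution = config$communities$resolution)
    state$partition <- part
    write_partition(part, file.path(out_dir, "partition.tsv"))
    emit("partition.tsv"); emit("partition.tsv.meta.json")
    sizes <- module_size_table(part)
    utils::write.csv(sizes, file.path(out_dir, "module_sizes.csv"),
                     row.names = FALSE)
    emit("module_sizes.csv")
    if (isTRUE(config$communities$bigclam$enabled)) {
      cover <- bigclam(state$network,
                       config$communities$bigclam$n_communities,
                       seed = config$seed)
      write_cover(cover, file.path(out_dir, "cover.json"))
      emit("cover.json")
    }
  })

  run_stage("enrichment", function() {
    for (cl in FEATURE_CLASSES) {
      res <- suppressWarnings(
        enrich(state$records, state$partition, cl,
               alpha = config$enrichment$alpha,
               p_adjust = config$enrichment$p_adjust))
      f <- sprintf("enrichment_%s.csv", cl)
      write_enrichment(res, file.path(out_dir, f))
      emit(f)
    }
  })

  run_stage("efficacy", function() {
    res <- symptom_resolution(state$records, state$partition,
                              min_support = config$efficacy$min_support)
    utils::write.csv(res, file.path(out_dir, "symptom_resolution.csv"),
                     row.names = FALSE)
    emit("symptom_resolution.csv")
  })

  run_stage("profiles", function() {
    sizes <- module_size_table(state$partition)
    top <- utils::head(sizes$module, config$profile$top_k_modules)
    for (mod in top) {
      prof <- module_profile(state$records, state$partition, mod,
                             alpha = config$enrichment$alpha,
                             top_k = config$profile$top_k_features,
                             min_support = config$efficacy$min_support)
      f <- sprintf("profile_module_%d.json", mod)
      write_module_profile(prof, file.path(out_dir, f))
      emit(f)
    }
  })

  digests <- lapply(artifacts, function(a) {
    p <- file.path(out_dir, a)
    list(file = a, md5 = unname(tools::md5sum(p)),
         bytes = file.info(p)$size)
  })
  manifest <- list(
    version = as.character(utils::packageVersion("psnstrat")),
    seed = config$seed,
    config = config,
    stages = stages,
    artifacts = digests
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
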