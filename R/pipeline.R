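#' Pipeline configuration
#'
#' Validates a configuration list (or YAML file) for the end-to-end
#' dynamic-risk-model pipeline. Unknown keys are rejected so typos never
#' silently fall back to defaults.
#'
#' Top-level keys (all optional except where noted):
#' * `seed`: integer master seed (default 1); all randomness derives
#'   from it.
#' * `cohort`: arguments for [cohort_config()] (`n_patients`, `n_days`,
#'   `n_ves`, `n_phq`, `missing_day_prob`, `activity_mixture`,
#'   `sleep_mixture`, `cancer_mix`, `risk_params`).
#' * `input`: `event_csv` and `patients_csv` paths to analyse an
#'   existing cohort instead of simulating one.
#' * `max_gap`: gap tolerance in days for run collapsing (default 2).
#' * `min_size`: smallest acceptable cluster (default 5).
#' * `threshold_grid`: candidate thresholds (default: off-diagonal
#'   distance deciles).
#' * `zero_cell_correction`: apply the Haldane-Anscombe correction in
#'   risk tables (default `FALSE`).
#' * `out_dir`: output directory (required by the `run_*` commands).
#'
#' @param config list or path to a YAML file.
#' @param seed optional seed overriding the configured one.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list(), seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  allowed <- c("seed", "cohort", "input", "max_gap", "min_size",
               "threshold_grid", "zero_cell_correction", "out_dir")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) {
    stop("unknown configuration key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cohort_allowed <- c("n_patients", "n_days", "n_ves", "n_phq",
                      "missing_day_prob", "activity_mixture",
                      "sleep_mixture", "cancer_mix", "risk_params")
  unknown <- setdiff(names(config$cohort), cohort_allowed)
  if (length(unknown)) {
    stop("unknown cohort key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(config$input)) {
    unknown <- setdiff(names(config$input), c("event_csv", "patients_csv"))
    if (length(unknown)) {
      stop("unknown input key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  config$seed <- as.integer(seed %||% config$seed %||% 1L)
  config$max_gap <- config$max_gap %||% 2
  config$min_size <- as.integer(config$min_size %||% 5L)
  config$zero_cell_correction <-
    isTRUE(config$zero_cell_correction %||% FALSE)
  structure(config, class = "pipeline_config")
}

as_pipeline_config <- function(cfg) {
  if (inherits(cfg, "pipeline_config")) cfg else pipeline_config(cfg)
}

cohort_from_config <- function(cfg) {
  args <- cfg$cohort %||% list()
  if (!is.null(args$risk_params)) {
    args$risk_params <- do.call(risk_params, args$risk_params)
  }
  for (nm in c("activity_mixture", "sleep_mixture", "cancer_mix")) {
    if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
  }
  args$seed <- derive_seed(cfg$seed, "cohort")
  do.call(cohort_config, args)
}

load_or_simulate <- function(cfg) {
  if (!is.null(cfg$input)) {
    list(log = read_event_log(cfg$input$event_csv),
         patients = read_patients(cfg$input$patients_csv),
         config = NULL)
  } else {
    generate_cohort(cohort_from_config(cfg))
  }
}

pipeline_domains <- function() {
  list(
    activity = list(activity = "daily_steps", scheme = steps_scheme(),
                    outcome = "vulnerable"),
    sleep = list(activity = "sleep_efficiency", scheme = sleep_scheme(),
                 outcome = "anxiety")
  )
}

# Distance + threshold selection + clustering + models + risk table for
# one domain (activity or sleep). The shared computational core of the
# stage commands.
domain_analysis <- function(cohort, labels, cfg, dom) {
  seqs <- state_sequences(cohort$log, dom$activity, dom$scheme)
  d <- distance_matrix(seqs)
  sel <- select_threshold(d, labels, dom$outcome,
                          grid = cfg$threshold_grid,
                          min_size = cfg$min_size)
  cl <- sel$clustering
  vseq <- visit_sequences(cohort$log, dom$activity, dom$scheme,
                          cfg$max_gap)
  vcase <- sub("#.*$", "", names(vseq))
  models <- list(all = heatmap_scores(discover_model(vseq)))
  for (i in seq_along(cl$clusters)) {
    models[[paste0("cluster_", i)]] <-
      heatmap_scores(discover_model(vseq[vcase %in% cl$clusters[[i]]]))
  }
  rt <- build_risk_table(cl, labels, dom$outcome,
                         universe = cohort$patients$case_id,
                         correction = cfg$zero_cell_correction)
  list(distance = d, selection = sel, clustering = cl, models = models,
       risk_table = rt,
       shares = clustering_share_table(cl, total = nrow(cohort$patients)))
}

pipeline_log <- function(..., quiet = FALSE) {
  if (!quiet) message(format(Sys.time(), "[%H:%M:%S] "), ...)
}

new_emitter <- function(quiet) {
  written <- character(0)
  list(
    emit = function(path) {
      pipeline_log("wrote ", path, quiet = quiet)
      written <<- c(written, path)
      path
    },
    files = function() written
  )
}

write_cluster_outputs <- function(res, ddir, em) {
  em$emit(write_distance_matrix(res$distance,
                                file.path(ddir, "distance.csv")))
  writeLines(export_clustering_json(res$clustering, res$selection),
             file.path(ddir, "clustering.json"))
  em$emit(file.path(ddir, "clustering.json"))
  write.csv(data.frame(threshold = res$selection$grid,
                       score = res$selection$scores),
            file.path(ddir, "thresholds.csv"), row.names = FALSE)
  em$emit(file.path(ddir, "thresholds.csv"))
}

write_model_outputs <- function(res, ddir, em) {
  for (mn in names(res$models)) {
    writeLines(export_dot(res$models[[mn]]),
               file.path(ddir, paste0("model_", mn, ".dot")))
    em$emit(file.path(ddir, paste0("model_", mn, ".dot")))
    writeLines(export_model_json(res$models[[mn]]),
               file.path(ddir, paste0("model_", mn, ".json")))
    em$emit(file.path(ddir, paste0("model_", mn, ".json")))
  }
}

write_risk_outputs <- function(res, outcome, ddir, em) {
  em$emit(write_risk_table(res$risk_table,
                           file.path(ddir, paste0("risk_", outcome,
                                                  ".csv"))))
  writeLines(risk_table_markdown(res$risk_table),
             file.path(ddir, paste0("risk_", outcome, ".md")))
  em$emit(file.path(ddir, paste0("risk_", outcome, ".md")))
}

pipeline_setup <- function(cfg, quiet) {
  cfg <- as_pipeline_config(cfg)
  if (is.null(cfg$out_dir)) stop("out_dir is required", call. = FALSE)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- load_or_simulate(cfg)
  list(cfg = cfg, cohort = cohort,
       labels = label_outcomes(cohort$patients),
       em = new_emitter(quiet))
}

#' Run pipeline stages
#'
#' The five commands orchestrate the methodology end to end, writing
#' their outputs under `out_dir` and logging every file they produce:
#'
#' * `run_simulate()`: generate the synthetic cohort and write
#'   `events.csv` and `patients.csv`.
#' * `run_cluster()`: distance matrices, outcome-driven threshold
#'   selection and QT clustering for the activity and sleep domains
#'   (`<domain>/distance.csv`, `<domain>/clustering.json`,
#'   `<domain>/thresholds.csv`).
#' * `run_discover()`: whole-cohort and per-cluster process models as
#'   DOT and JSON (`<domain>/model_*.dot|json`).
#' * `run_risk()`: dual event/complement risk tables for the behaviour
#'   strata of each domain and for cancer type
#'   (`<domain>/risk_*.csv|md`, `cancer_risk_vulnerability.csv`).
#' * `run_pipeline()`: all of the above plus `summary.md` (cluster
#'   sizes with computed shares) and `provenance.yaml` (seed, config
#'   hash, package version).
#'
#' Given the same configuration and seed the output tree is
#' byte-identical across runs; all randomness flows from the single
#' configured seed through named substreams.
#'
#' @param cfg a [pipeline_config()] (or list/YAML path coerced by it).
#' @param quiet suppress progress messages.
#' @return `run_pipeline()` returns (invisibly) a list with the cohort,
#'   labels, per-domain analyses (`distance`, `selection`, `clustering`,
#'   `models`, `risk_table`, `shares`), the cancer-type risk table and
#'   the paths of every file written. The stage commands return their
#'   stage's results invisibly.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  st <- pipeline_setup(cfg, quiet)
  cfg <- st$cfg
  em <- st$em
  em$emit(write_event_log(st$cohort$log,
                          file.path(cfg$out_dir, "events.csv")))
  em$emit(write_patients(st$cohort$patients,
                         file.path(cfg$out_dir, "patients.csv")))

  doms <- pipeline_domains()
  results <- list()
  summary_lines <- c("# Pipeline summary", "",
                     sprintf("Patients: %d", nrow(st$cohort$patients)), "")
  for (dn in names(doms)) {
    pipeline_log("analysing ", dn, " domain", quiet = quiet)
    ddir <- file.path(cfg$out_dir, dn)
    dir.create(ddir, showWarnings = FALSE)
    res <- domain_analysis(st$cohort, st$labels, cfg, doms[[dn]])
    write_cluster_outputs(res, ddir, em)
    write_model_outputs(res, ddir, em)
    write_risk_outputs(res, doms[[dn]]$outcome, ddir, em)
    summary_lines <- c(summary_lines,
                       sprintf("## %s behaviour groups (threshold %.4f)",
                               dn, res$clustering$threshold), "",
                       "| Group | N | % Total |", "|---|---|---|",
                       sprintf("| %s | %d | %.1f%% |", res$shares$group,
                               res$shares$n, res$shares$pct), "")
    results[[dn]] <- res
  }

  cancer_rt <- categorical_exposure_risk(st$cohort$patients, "cancer_type",
                                         st$labels, "vulnerable",
                                         correction = cfg$zero_cell_correction)
  em$emit(write_risk_table(cancer_rt,
                           file.path(cfg$out_dir,
                                     "cancer_risk_vulnerability.csv")))
  writeLines(summary_lines, file.path(cfg$out_dir, "summary.md"))
  em$emit(file.path(cfg$out_dir, "summary.md"))

  hash_cfg <- unclass(cfg)
  hash_cfg$out_dir <- NULL  # analytic parameters only, not file layout
  prov <- list(seed = cfg$seed,
               config_sha = config_hash(yaml::as.yaml(hash_cfg)),
               package_version = as.character(utils::packageVersion("dynrisk")),
               r_version = paste(R.version$major, R.version$minor,
                                 sep = "."))
  writeLines(yaml::as.yaml(prov), file.path(cfg$out_dir, "provenance.yaml"))
  em$emit(file.path(cfg$out_dir, "provenance.yaml"))

  invisible(list(cohort = st$cohort, labels = st$labels,
                 domains = results, cancer_risk = cancer_rt,
                 files = em$files()))
}

#' @rdname run_pipeline
#' @export
run_simulate <- function(cfg, quiet = FALSE) {
  cfg <- as_pipeline_config(cfg)
  if (is.null(cfg$out_dir)) stop("out_dir is required", call. = FALSE)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  em <- new_emitter(quiet)
  cohort <- generate_cohort(cohort_from_config(cfg))
  em$emit(write_event_log(cohort$log, file.path(cfg$out_dir, "events.csv")))
  em$emit(write_patients(cohort$patients,
                         file.path(cfg$out_dir, "patients.csv")))
  invisible(cohort)
}

run_stage <- function(cfg, quiet, writer) {
  st <- pipeline_setup(cfg, quiet)
  doms <- pipeline_domains()
  results <- list()
  for (dn in names(doms)) {
    ddir <- file.path(st$cfg$out_dir, dn)
    dir.create(ddir, showWarnings = FALSE)
    res <- domain_analysis(st$cohort, st$labels, st$cfg, doms[[dn]])
    writer(res, doms[[dn]], ddir, st$em)
    results[[dn]] <- res
  }
  invisible(results)
}

#' @rdname run_pipeline
#' @export
run_cluster <- function(cfg, quiet = FALSE) {
  run_stage(cfg, quiet, function(res, dom, ddir, em) {
    write_cluster_outputs(res, ddir, em)
  })
}

#' @rdname run_pipeline
#' @export
run_discover <- function(cfg, quiet = FALSE) {
  run_stage(cfg, quiet, function(res, dom, ddir, em) {
    write_model_outputs(res, ddir, em)
  })
}

#' @rdname run_pipeline
#' @export
run_risk <- function(cfg, quiet = FALSE) {
  run_stage(cfg, quiet, function(res, dom, ddir, em) {
    write_risk_outputs(res, dom$outcome, ddir, em)
  })
}

# Small stable polynomial hash of the config text; provenance only.
config_hash <- function(txt) {
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
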