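#' Configuration of a full pipeline run
#'
#' Validates every stage's parameters before any stage executes. Stage
#' seeds are derived from the master seed plus the stage ordinal
#' (simulate = +1, balance = +4, split = +5), so stages can be re-run
#' independently yet a fixed master seed reproduces the whole run.
#'
#' @param out_dir Output directory for stage CSV/JSON artifacts.
#' @param organization `"WHO"`, `"GOAL3"` or `"both"` — which cut-off
#'   tables to run (each gets its own branch of alarms, patterns and
#'   models).
#' @param cohort A [cohort_config()] (its own seed is overridden by the
#'   derived simulate seed).
#' @param window_hours,n_segments Pre-event window geometry.
#' @param eps,min_pts DBSCAN parameters for pattern extraction.
#' @param families Classifier families to compare.
#' @param train_fraction Train share of the patient split.
#' @param seed Master seed.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("alarmscape_run"),
                       organization = "WHO",
                       cohort = cohort_config(),
                       window_hours = 8, n_segments = 4,
                       eps = 0.5, min_pts = 10,
                       families = c("random_forest", "svm",
                                    "decision_tree"),
                       train_fraction = 0.7, seed = 1L) {
  organization <- match.arg(tolower(organization), c("who", "goal3", "both"))
  stopifnot(inherits(cohort, "cohort_config"), window_hours > 0,
            n_segments >= 1, eps > 0, min_pts >= 1,
            train_fraction > 0, train_fraction < 1)
  families <- match.arg(families, c("random_forest", "svm", "decision_tree"),
                        several.ok = TRUE)
  structure(list(out_dir = out_dir, organization = organization,
                 cohort = cohort, window_hours = window_hours,
                 n_segments = n_segments, eps = eps, min_pts = min_pts,
                 families = families, train_fraction = train_fraction,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; the `cohort` key nests
#' [cohort_config()] arguments.
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cohort <- do.call(cohort_config, raw$cohort %||% list())
  raw$cohort <- cohort
  do.call(run_config, raw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_seed <- function(master, ordinal) as.integer(master + ordinal)

#' Run the full alarm-pattern pipeline
#'
#' Executes simulate -> detect alarms -> window -> extract patterns ->
#' train/compare in order, writing each stage's tabular output as CSV
#' under `config$out_dir` before the next stage starts, and finishing
#' with a JSON run manifest (config snapshot, derived seeds, per-stage
#' row counts and wall-clock). With `organization = "both"` the WHO and
#' GOAL3 branches run side by side from the same simulated cohort.
#'
#' @param config A [run_config()].
#' @param pattern_specs Optional pattern tibble override for the
#'   simulator; defaults to the branch-matched [default_pattern_specs()]
#'   (WHO specs when both branches run).
#' @return The manifest, invisibly; also written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config, pattern_specs = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  orgs <- if (config$organization == "both") c("WHO", "GOAL3")
          else toupper(config$organization)
  sim_org <- orgs[[1]]
  specs <- pattern_specs %||% default_pattern_specs(sim_org)
  stage <- function(name, f) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(f(), error = function(e) {
      writeLines(paste("FAILED at stage:", name, "-", conditionMessage(e)),
                 file.path(config$out_dir, "FAILED"))
      stop("pipeline failed at stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
    list(result = res, seconds = proc.time()[["elapsed"]] - t0)
  }
  manifest <- list(config = snapshot_config(config),
                   seeds = list(simulate = stage_seed(config$seed, 1)),
                   stages = list())

  cfg <- config$cohort
  cfg$seed <- stage_seed(config$seed, 1)
  sim <- stage("simulate", function() {
    coh <- generate_cohort(cfg, specs, builtin_cutoffs(sim_org))
    write_cohort_csv(coh, file.path(config$out_dir, "cohort"))
    coh
  })
  cohort <- sim$result
  manifest$stages$simulate <- list(seconds = sim$seconds,
                                   n_patients = nrow(cohort$manifest))

  events <- pseudo_events(cohort$manifest)
  for (org in orgs) {
    tag <- tolower(org)
    al <- stage(paste0("alarms_", tag), function() {
      ep <- detect_cohort_episodes(cohort, builtin_cutoffs(org))
      readr::write_csv(ep, file.path(config$out_dir,
                                     paste0("alarms_", tag, ".csv")))
      ep
    })
    episodes <- al$result
    manifest$stages[[paste0("alarms_", tag)]] <-
      list(seconds = al$seconds, n_episodes = nrow(episodes))

    wi <- stage(paste0("windows_", tag), function() {
      w <- window_alarms(episodes, events, config$window_hours)
      readr::write_csv(w, file.path(config$out_dir,
                                    paste0("windowed_", tag, ".csv")))
      seg <- segment_summary(w, config$window_hours, config$n_segments)
      readr::write_csv(dplyr::select(seg, -"duration_hist"),
                       file.path(config$out_dir,
                                 paste0("segments_", tag, ".csv")))
      w
    })
    windowed <- wi$result
    manifest$stages[[paste0("windows_", tag)]] <-
      list(seconds = wi$seconds, n_windowed = nrow(windowed))

    pa <- stage(paste0("patterns_", tag), function() {
      f <- extract_pattern_features(windowed, eps = config$eps,
                                    min_pts = config$min_pts)
      readr::write_csv(f, file.path(config$out_dir,
                                    paste0("features_", tag, ".csv")))
      f
    })
    features <- pa$result
    manifest$stages[[paste0("patterns_", tag)]] <-
      list(seconds = pa$seconds, n_feature_rows = nrow(features))

    tr <- stage(paste0("train_", tag), function() {
      ds <- assemble_dataset(features, cohort$manifest, balance = TRUE,
                             seed = stage_seed(config$seed, 4))
      cmp <- compare_models(purrr::map(config$families, model_spec),
                            ds, config$train_fraction,
                            seed = stage_seed(config$seed, 5))
      readr::write_csv(tibble::as_tibble(cmp),
                       file.path(config$out_dir,
                                 paste0("model_comparison_", tag, ".csv")))
      evals <- attr(cmp, "evaluations")
      report <- purrr::map(evals, function(ev) {
        list(family = ev$family, accuracy = ev$accuracy,
             auc = as.list(ev$auc),
             per_class = ev$metrics,
             confusion = as.data.frame(ev$confusion), notes = ev$notes)
      })
      jsonlite::write_json(report,
                           file.path(config$out_dir,
                                     paste0("report_", tag, ".json")),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
      cmp
    })
    manifest$stages[[paste0("train_", tag)]] <-
      list(seconds = tr$seconds,
           accuracy = stats::setNames(tr$result$accuracy,
                                      tr$result$family))
  }
  manifest$seeds$balance <- stage_seed(config$seed, 4)
  manifest$seeds$split <- stage_seed(config$seed, 5)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

snapshot_config <- function(config) {
  s <- unclass(config)
  s$cohort <- unclass(s$cohort)
  s
}

#' Write / read a cohort as per-patient CSV files plus a manifest
#'
#' One CSV per patient (`patient_id`, `timestamp` in epoch seconds,
#' `ecghr`, `ecgrr`, `spo2`; empty field = missing sample) and a
#' `manifest.csv` with `patient_id`, `age_months`, `sex`, `cie_type`,
#' `cie_time`, `rec_start`, `rec_end`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Directory to create/populate.
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$manifest, file.path(dir, "manifest.csv"))
  for (pid in cohort$manifest$patient_id) {
    readr::write_csv(
      tibble::add_column(cohort$series[[pid]], patient_id = pid,
                         .before = 1),
      file.path(dir, paste0(pid, ".csv")))
  }
  invisible(dir)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(dir) {
  manifest <- readr::read_csv(file.path(dir, "manifest.csv"),
                              show_col_types = FALSE)
  series <- stats::setNames(purrr::map(manifest$patient_id, function(pid) {
    dplyr::select(readr::read_csv(file.path(dir, paste0(pid, ".csv")),
                                  show_col_types = FALSE), -"patient_id")
  }), manifest$patient_id)
  structure(list(manifest = manifest, series = series),
            class = "synthetic_cohort")
}
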