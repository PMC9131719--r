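#' Default run configuration
#'
#' The full set of pipeline settings with their defaults: master seed,
#' cohort model and size, measurement protocol, stimulus geometry,
#' population distributions, and statistics options. Every random operation
#' in the pipeline traces back to the single `seed` through named
#' substreams (subject, session, measure).
#'
#' @return A nested named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    seed = 1L,
    cohort = list(model = "null", n = 10L),
    protocol = list(post_times_min = c(0, 10, 20, 30, 40),
                    phase_repetitions = 8L, qiocsf_trials = 100L,
                    measures = c("phase", "iocsf"), theta0 = 22.5),
    stimulus = list(extent_deg = 12.8, pixels_per_degree = 40,
                    octave_bandwidth = 1),
    population = default_population(),
    statistics = list(tail = "one", sphericity = "auto",
                      alpha = 0.05, target_power = 0.8)),
    class = "run_config")
}

validate_config <- function(cfg) {
  problems <- character()
  defaults <- unclass(default_run_config())
  check_keys <- function(x, ref, path) {
    extra <- setdiff(names(x), names(ref))
    if (length(extra))
      problems <<- c(problems, paste0("unknown key(s) ", path,
                                      paste(extra, collapse = ", ")))
    for (nm in intersect(names(x), names(ref)))
      if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])))
        check_keys(x[[nm]], ref[[nm]], paste0(path, nm, "."))
  }
  check_keys(unclass(cfg), defaults, "")
  lp <- cfg$population$lapse
  if (!is.null(lp) && (lp < 0 || lp >= 0.1))
    problems <- c(problems, "population.lapse must lie in [0, 0.1)")
  if (!cfg$cohort$model %in% c("null", "deprivation"))
    problems <- c(problems, "cohort.model must be 'null' or 'deprivation'")
  if (cfg$cohort$n < 2) problems <- c(problems, "cohort.n must be >= 2")
  if (!cfg$statistics$tail %in% c("one", "two"))
    problems <- c(problems, "statistics.tail must be 'one' or 'two'")
  if (!cfg$statistics$sphericity %in% c("auto", "always", "never"))
    problems <- c(problems,
                  "statistics.sphericity must be auto/always/never")
  if (!all(cfg$protocol$measures %in% c("phase", "iocsf")))
    problems <- c(problems, "protocol.measures must be phase and/or iocsf")
  if (length(problems))
    stop("invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  cfg
}

#' Load a run configuration from a YAML file
#'
#' Reads plain-text key-value settings, fills every omitted key from
#' [default_run_config()], rejects unknown keys, and validates ranges
#' (itemising every violation). An empty file yields the defaults.
#'
#' @param path Path to a YAML file.
#' @return A validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  if (!is.null(user)) {
    merged <- utils::modifyList(unclass(cfg), user)
    cfg <- structure(merged, class = "run_config")
  }
  validate_config(cfg)
}

#' Save a run configuration as YAML
#'
#' Round-trips losslessly through [load_config()].
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full simulate-and-analyse pipeline from a configuration
#'
#' Generates the cohort, simulates the pre/post session schedule, and runs
#' the session statistics for every configured measure.
#'
#' @param config A `run_config` (defaults when omitted).
#' @return A list with `cohort`, `dataset`, and `analyses` (one
#'   [analyze_sessions()] result per measure, named `phase` / `aulio`).
#' @export
run_pipeline <- function(config = default_run_config()) {
  validate_config(config)
  cohort <- make_cohort(config$cohort$n, config$cohort$model,
                        population_params = config$population,
                        seed = config$seed)
  protocol <- experiment_protocol(
    post_times_min = config$protocol$post_times_min,
    phase_repetitions = config$protocol$phase_repetitions,
    qiocsf_trials = config$protocol$qiocsf_trials,
    measures = config$protocol$measures,
    theta0 = config$protocol$theta0)
  dataset <- simulate_experiment(cohort, protocol)
  analyses <- list()
  if ("phase" %in% config$protocol$measures)
    analyses$phase <- analyze_sessions(dataset, "phase",
                                       sphericity = config$statistics$sphericity)
  if ("iocsf" %in% config$protocol$measures)
    analyses$aulio <- analyze_sessions(dataset, "aulio",
                                       sphericity = config$statistics$sphericity)
  list(cohort = cohort, dataset = dataset, analyses = analyses)
}

#' Write a complete experiment bundle to disk
#'
#' Deterministic plain-text layout: `cohort.json` (model, seed and
#' population settings), `phase_trials.csv`, `qiocsf_trials.csv`,
#' `session_summary.csv` (one row per subject and session), `report.json`
#' (the headline statistics per measure) and `manifest.json` listing every
#' written file with its MD5 content hash. Identical configuration and seed
#' give byte-identical files.
#'
#' @param dataset An [simulate_experiment()] result.
#' @param analyses Named list of [analyze_sessions()] results (as returned
#'   in `run_pipeline()$analyses`); may be empty.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest tibble (`file`, `md5`).
#' @export
write_experiment_bundle <- function(dataset, analyses = list(), out_dir) {
  stopifnot(inherits(dataset, "experiment_dataset"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  p <- function(f) file.path(out_dir, f)

  jsonlite::write_json(
    list(model = dataset$model, seed = dataset$cohort_seed,
         n_subjects = dplyr::n_distinct(dataset$data$subject_id),
         sessions = dataset$protocol$session_labels),
    p("cohort.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(dataset$phase_trials, p("phase_trials.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$qiocsf_trials, p("qiocsf_trials.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$data, p("session_summary.csv"),
                   row.names = FALSE)
  report <- lapply(analyses, function(a) as.list(glance(a)))
  jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                       digits = NA)

  files <- c("cohort.json", "phase_trials.csv", "qiocsf_trials.csv",
             "session_summary.csv", "report.json")
  manifest <- tibble::tibble(
    file = files,
    md5 = unname(tools::md5sum(vapply(files, p, ""))))
  jsonlite::write_json(manifest, p("manifest.json"), digits = NA)
  invisible(manifest)
}

#' Read the per-session summary back from a bundle
#'
#' @param out_dir Bundle directory.
#' @return The `session_summary.csv` tibble.
#' @export
read_session_summary <- function(out_dir) {
  tibble::as_tibble(utils::read.csv(file.path(out_dir,
                                              "session_summary.csv")))
}
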