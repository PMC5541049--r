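#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. Inputs may
#' be given as CSV paths (`evidence_path`, `attributes_path`, `burden_path`)
#' or left `NULL`, in which case the synthetic generator supplies them (for
#' evidence/attributes) or the packaged 2010 GBD table is used (for burden).
#'
#' @param evidence_path,attributes_path,burden_path input CSVs, or `NULL`.
#' @param output_dir directory for the report bundle.
#' @param grid positive rubric grid.
#' @param seed integer seed forwarded to the synthetic generator when inputs
#'   are simulated.
#' @param all_cause_dalys all-cause DALY total (thousands) for relative
#'   impacts.
#' @param synth a `synth_config` used when simulating; its seed is overridden
#'   by `seed`.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(evidence_path = NULL, attributes_path = NULL,
                            burden_path = NULL, output_dir = "climsens-out",
                            grid = rubric_grid(), seed = 20170802,
                            all_cause_dalys = 2490385,
                            synth = synth_config(seed = seed)) {
  if (all_cause_dalys <= 0) value_error("all_cause_dalys must be positive")
  for (p in c(evidence_path, attributes_path, burden_path))
    if (!is.null(p) && !file.exists(p))
      value_error(sprintf("input file does not exist: %s", p))
  if (xor(is.null(evidence_path), is.null(attributes_path)))
    value_error("evidence_path and attributes_path must be given together")
  structure(list(evidence_path = evidence_path,
                 attributes_path = attributes_path,
                 burden_path = burden_path, output_dir = output_dir,
                 grid = grid, seed = seed,
                 all_cause_dalys = all_cause_dalys, synth = synth),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys mirror the arguments of [pipeline_config()]; unknown keys
#' are rejected.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    validation_error(sprintf("unknown config key(s): %s",
                             paste(bad, collapse = ", ")))
  if (!is.null(raw$seed) && is.null(raw$synth))
    raw$synth <- synth_config(seed = raw$seed)
  do.call(pipeline_config, raw)
}

pipeline_log <- function(con, stage, msg) {
  line <- sprintf("[%s] %-10s %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                  stage, msg)
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full assessment pipeline
#'
#' Orchestrates simulate/load -> score -> profile -> associate -> burden ->
#' report. Writes, under `config$output_dir`: the per-pair median and profile
#' summary CSVs, the association-model report (`models.json`), the burden
#' report (`burden.json`), a combined `report.json`, and `run.log` recording
#' package version, configuration and row counts at every stage. JSON is
#' pretty-printed for diff-stability. Deterministic given inputs and seed.
#'
#' @param config a `pipeline_config` (or path to a YAML file).
#' @return invisibly, a list with `profiles`, `summary`, `associations`,
#'   `burden` and the written `paths`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config"))
    value_error("config must be a pipeline_config or a YAML path")
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$output_dir, "run.log")
  con <- file(log_path, open = "wt")
  on.exit(close(con))
  log <- function(stage, msg) pipeline_log(con, stage, msg)
  log("start", sprintf("climsens %s; seed %s",
                       as.character(utils::packageVersion("climsens")),
                       config$seed))

  if (is.null(config$evidence_path)) {
    synth <- config$synth
    synth$seed <- config$seed
    sim <- simulate_study(synth)
    evidence <- sim$evidence
    attributes <- validate_attributes(sim$attributes,
                                      n_countries_max = synth$n_countries_max)
    log("simulate", sprintf("%d pathogens, %d evidence records",
                            nrow(attributes), nrow(evidence)))
  } else {
    evidence <- read_evidence(config$evidence_path, grid = config$grid)
    attributes <- read_attributes(config$attributes_path)
    log("load", sprintf("%d pathogens, %d evidence records",
                        nrow(attributes), nrow(evidence)))
  }

  medians <- aggregate_evidence(evidence, grid = config$grid)
  log("score", sprintf("%d (pathogen, driver) pairs with records, %d positive",
                       nrow(medians), sum(medians$positive)))

  profiles <- build_profiles(medians, roster = attributes$pathogen_id)
  summary <- cohort_summary(profiles, attributes)
  log("profile", sprintf("%d of %d pathogens climate-sensitive",
                         summary$n_sensitive, summary$n_total))

  assoc <- climate_associations(profiles, attributes)
  log("associate", sprintf("%d association results",
                           nrow(as.data.frame(assoc))))

  burden_path <- config$burden_path %||%
    system.file("extdata", "gbd_burden_2010.csv", package = "climsens",
                mustWork = TRUE)
  burden_tab <- read_burden_table(burden_path)
  burden <- attribute_burden(burden_tab,
                             all_cause_total = config$all_cause_dalys)
  log("burden", sprintf("%d diseases, %d climate-sensitive",
                        burden$n_diseases, burden$n_any_driver))

  paths <- list(
    medians = file.path(config$output_dir, "pair_medians.csv"),
    profiles = file.path(config$output_dir, "profiles.csv"),
    models = file.path(config$output_dir, "models.json"),
    burden = file.path(config$output_dir, "burden.json"),
    report = file.path(config$output_dir, "report.json"),
    log = log_path
  )
  write_profiles(profiles, paths$medians, paths$profiles)
  assoc_df <- as.data.frame(assoc)
  jsonlite::write_json(assoc_df, paths$models, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  jsonlite::write_json(
    burden[c("n_diseases", "n_any_driver", "n_primary", "n_secondary_only",
             "total_dalys", "sensitive_dalys", "primary_sensitive_dalys",
             "fraction_sensitive", "fraction_primary_sensitive")],
    paths$burden, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report <- list(
    n_pathogens = summary$n_total,
    n_sensitive = summary$n_sensitive,
    n_has_primary = summary$n_has_primary,
    n_has_secondary = summary$n_has_secondary,
    driver_frequencies = driver_frequencies(summary),
    burden = list(fraction_sensitive = burden$fraction_sensitive,
                  fraction_primary_sensitive =
                    burden$fraction_primary_sensitive),
    seed = config$seed
  )
  jsonlite::write_json(report, paths$report, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log("report", sprintf("bundle written to %s", config$output_dir))

  invisible(list(profiles = profiles, summary = summary, associations = assoc,
                 burden = burden, paths = paths))
}
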