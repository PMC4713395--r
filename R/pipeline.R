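#' Run the full simulate-score-classify-filter-analyze pipeline
#'
#' Chains every stage of the analysis on a synthetic cohort (or an existing
#' cohort CSV), writing each stage's artifact plus a run manifest. Rerunning
#' with the same configuration reproduces byte-identical CSV outputs.
#'
#' Artifacts written under `out_dir`: `cohort.csv` (simulated or copied
#' input), `scored.csv`, `classified.csv`, `included.csv`,
#' `flowchart.json`, the analysis tables (see [write_report()]) and
#' `manifest.json` (seed, configuration hash, record counts per stage).
#'
#' @param config A [simulation_config()]; ignored when `cohort_csv` is
#'   given.
#' @param out_dir Output directory, created if absent.
#' @param cohort_csv Optional path to an existing cohort CSV to analyse
#'   instead of simulating.
#' @param verbose Log stage progress to standard error.
#' @return The [intensity_analysis()] object, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config = simulation_config(), out_dir,
                         cohort_csv = NULL, verbose = TRUE) {
  log_line <- function(stage, msg) {
    if (verbose) message(sprintf("[%s] %s", stage, msg))
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  if (is.null(cohort_csv)) {
    log_line("simulate", sprintf("generating %d stays (seed %d)",
                                 config$n_stays, config$seed))
    cohort <- generate_cohort(config)
  } else {
    log_line("simulate", paste("reading cohort from", cohort_csv))
    cohort <- read_cohort(cohort_csv)
  }
  write_cohort(cohort, file.path(out_dir, "cohort.csv"))

  log_line("score", "computing SAPS II scores")
  scored <- score_cohort(cohort)
  utils::write.csv(scored, file.path(out_dir, "scored.csv"),
                   row.names = FALSE, na = "")

  log_line("classify", "assigning treatment-intensity groups")
  classified <- classify_cohort(scored)
  utils::write.csv(classified, file.path(out_dir, "classified.csv"),
                   row.names = FALSE, na = "")

  log_line("filter", "applying inclusion rules")
  filtered <- apply_inclusion(classified)
  utils::write.csv(filtered$included, file.path(out_dir, "included.csv"),
                   row.names = FALSE, na = "")
  jsonlite::write_json(filtered$flowchart,
                       file.path(out_dir, "flowchart.json"),
                       auto_unbox = TRUE, digits = NA)
  log_line("filter", sprintf("%d of %d stays included",
                             filtered$flowchart$n_included,
                             filtered$flowchart$n_input))

  log_line("analyze", "building stratified tables")
  fit <- intensity_analysis(filtered$included)
  write_report(fit, out_dir)

  cfg_yaml <- yaml::as.yaml(unclass(config))
  cfg_file <- tempfile(); on.exit(unlink(cfg_file))
  writeLines(cfg_yaml, cfg_file)
  manifest <- list(
    seed = if (is.null(cohort_csv)) config$seed else NA,
    config_hash = unname(tools::md5sum(cfg_file)),
    counts = list(simulated = nrow(cohort), scored = nrow(scored),
                  classified = nrow(classified),
                  included = filtered$flowchart$n_included),
    flowchart = filtered$flowchart)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  log_line("analyze", paste("artifacts written to", out_dir))
  invisible(fit)
}

#' Read / write a simulation configuration as YAML
#'
#' @param config A [simulation_config()] object.
#' @param path YAML file path.
#' @return `read_sim_config()`: a validated `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  x$mortality_multipliers <- as.vector(x$mortality_multipliers)
  # named atomic vectors must become maps or YAML drops the names
  x$support_model$catecholamine$agents <-
    as.list(x$support_model$catecholamine$agents)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  defaults <- simulation_config()
  for (f in names(x)) defaults[[f]] <- x[[f]]
  if (!is.null(x$mortality_multipliers))
    defaults$mortality_multipliers <-
      multiplier_matrix(matrix(unlist(x$mortality_multipliers), 6, 4))
  if (!is.null(x$age_mixture))
    defaults$age_mixture <- lapply(x$age_mixture, unlist)
  if (!is.null(x$support_model)) {
    sm <- rapply(x$support_model, unlist, how = "replace")
    sm$catecholamine$agents <- unlist(x$support_model$catecholamine$agents)
    defaults$support_model <- utils::modifyList(default_support_model(), sm)
  }
  defaults$n_stays <- as.integer(defaults$n_stays)
  defaults$seed <- as.integer(defaults$seed)
  validate_sim_config(defaults)
  defaults
}
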