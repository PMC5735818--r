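#' Run configuration
#'
#' Validated description of a full reproduction run: which scenarios to
#' build (or which SBML files to import), the simulation settings, the
#' readouts to analyse, the output directory and the seed. The exact
#' configuration is serialized next to every output for provenance.
#'
#' @param scenarios Character vector of scenario names.
#' @param sbml_paths Optional named character vector (names = scenario
#'   labels) of SBML files to import instead of building.
#' @param ledger Parameter ledger; default [default_ledger()].
#' @param settings [simulation_settings()] for the runs.
#' @param readouts Canonical readout names to analyse.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed (used only when parameter sampling is
#'   requested).
#' @param sample_cv Coefficient of variation for optional ledger sampling
#'   (0 = use the ledger as-is).
#' @return List of class `sbn_runconfig`.
#' @export
run_config <- function(scenarios = c("SF", "DF", "DF_miRNA"),
                       sbml_paths = NULL,
                       ledger = default_ledger(),
                       settings = simulation_settings(),
                       readouts = names(default_name_map()),
                       out_dir = "follisim_out",
                       seed = 1L, sample_cv = 0) {
  known <- c("SF", "DF", "DF_miRNA")
  bad <- setdiff(scenarios, known)
  if (length(bad))
    stop("unknown scenario name: ", paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(sbml_paths)) {
    missing <- sbml_paths[!file.exists(sbml_paths)]
    if (length(missing))
      stop("SBML input not found: ", paste(missing, collapse = ", "),
           call. = FALSE)
  }
  structure(list(scenarios = scenarios, sbml_paths = sbml_paths,
                 ledger = ledger, settings = settings, readouts = readouts,
                 out_dir = out_dir, seed = as.integer(seed),
                 sample_cv = sample_cv),
            class = "sbn_runconfig")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with any of the fields of [run_config()]
#'   (`scenarios`, `sbml_paths`, `settings`, `readouts`, `out_dir`, `seed`,
#'   `sample_cv`, plus `rates`/`initials` ledger overrides).
#' @return An `sbn_runconfig`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  ledger <- default_ledger()
  if (!is.null(cfg$rates)) ledger$rates[names(cfg$rates)] <- unlist(cfg$rates)
  if (!is.null(cfg$initials))
    ledger$initials[names(cfg$initials)] <- unlist(cfg$initials)
  st <- do.call(simulation_settings, c(cfg$settings))
  run_config(
    scenarios = if (is.null(cfg$scenarios)) c("SF", "DF", "DF_miRNA") else unlist(cfg$scenarios),
    sbml_paths = if (is.null(cfg$sbml_paths)) NULL else unlist(cfg$sbml_paths),
    ledger = ledger, settings = st,
    readouts = if (is.null(cfg$readouts)) names(default_name_map()) else unlist(cfg$readouts),
    out_dir = if (is.null(cfg$out_dir)) "follisim_out" else cfg$out_dir,
    seed = if (is.null(cfg$seed)) 1L else cfg$seed,
    sample_cv = if (is.null(cfg$sample_cv)) 0 else cfg$sample_cv)
}

config_ledger <- function(config) {
  if (config$sample_cv > 0)
    sample_parameters(config$ledger, config$seed, config$sample_cv)
  else config$ledger
}

config_models <- function(config) {
  ledger <- config_ledger(config)
  models <- list()
  for (sc in config$scenarios) {
    models[[sc]] <- if (!is.null(config$sbml_paths) && sc %in% names(config$sbml_paths))
      read_sbml(config$sbml_paths[[sc]])
    else
      build_scenario(scenario_spec(sc, seed = config$seed), ledger)
  }
  models
}

save_config <- function(config, dir) {
  cfg <- list(scenarios = config$scenarios,
              sbml_paths = as.list(config$sbml_paths),
              settings = unclass(config$settings),
              readouts = config$readouts, out_dir = config$out_dir,
              seed = config$seed, sample_cv = config$sample_cv,
              rates = as.list(config$ledger$rates),
              initials = as.list(config$ledger$initials))
  yaml::write_yaml(cfg, file.path(dir, "config_used.yaml"))
}

#' Build scenario models and export them as SBML
#'
#' Builds (or imports) every configured scenario, writes one SBML file and
#' a combined structural-summary CSV to the output directory, and reports
#' validation.
#'
#' @param config An `sbn_runconfig`.
#' @return Invisibly, a list with `models`, `summaries` (data frame) and
#'   `clean` (logical: all validations error-free).
#' @export
run_build <- function(config = run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  save_config(config, config$out_dir)
  models <- config_models(config)
  summaries <- list(); clean <- TRUE
  for (sc in names(models)) {
    rep <- validate_model(models[[sc]])
    clean <- clean && length(rep$errors) == 0L
    path <- file.path(config$out_dir, paste0(sc, ".sbml.xml"))
    write_sbml(models[[sc]], path)
    summaries[[sc]] <- cbind(scenario = sc,
                             as.data.frame(model_summary(models[[sc]], path)))
  }
  summaries <- do.call(rbind, summaries)
  utils::write.csv(summaries, file.path(config$out_dir, "model_summaries.csv"),
                   row.names = FALSE)
  message(sprintf("built %d scenario model(s); validation %s",
                  length(models), if (clean) "clean" else "FAILED"))
  invisible(list(models = models, summaries = summaries, clean = clean))
}

#' Simulate the configured scenarios
#'
#' @param config An `sbn_runconfig`.
#' @return Invisibly, a named list of `sbn_timecourse` objects (also
#'   written as tidy CSVs with JSON settings sidecars).
#' @export
run_simulate <- function(config = run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  save_config(config, config$out_dir)
  models <- config_models(config)
  runs <- list()
  for (sc in names(models)) {
    tc <- simulate(models[[sc]], settings = config$settings)
    write_timecourse_csv(tc, file.path(config$out_dir, paste0(sc, "_timecourse.csv")))
    runs[[sc]] <- tc
    message(sprintf("simulated %s: %d species over [%g, %g] s", sc,
                    nrow(tc$values), config$settings$t_start, config$settings$t_end))
  }
  invisible(runs)
}

#' Compare simulated scenarios
#'
#' @param config An `sbn_runconfig` naming at least two scenarios.
#' @param runs Optional pre-computed named list of time courses (otherwise
#'   [run_simulate()] is called).
#' @return Invisibly, a list with the comparison `table` and the
#'   qualitative `checks` (also written as CSV and JSON).
#' @export
run_compare <- function(config = run_config(), runs = NULL) {
  if (length(config$scenarios) < 2L)
    stop("comparison requires at least two scenarios", call. = FALSE)
  if (is.null(runs)) runs <- run_simulate(config)
  tab <- compare_scenarios(runs, config$readouts)
  cs <- default_check_set()
  cs <- cs[cs$readout %in% config$readouts &
             cs$a %in% names(runs) & cs$b %in% names(runs) &
             (cs$type != "monotone_peak" |
                all(c("SF", "DF", "DF_miRNA") %in% names(runs))), ]
  checks <- qualitative_check(tab, runs, checks = cs)
  utils::write.csv(as.data.frame(tab),
                   file.path(config$out_dir, "comparison_table.csv"),
                   row.names = FALSE)
  jsonlite::write_json(checks, file.path(config$out_dir, "checks.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  message(sprintf("%d / %d qualitative checks pass",
                  sum(checks$pass, na.rm = TRUE), sum(!is.na(checks$pass))))
  invisible(list(table = tab, checks = checks))
}

#' One-shot reproduction pipeline
#'
#' Build or import the three scenario models, simulate them, compute the
#' comparison table and qualitative checks, and render the three-line
#' comparison figures. Deterministic for a fixed configuration.
#'
#' @param config An `sbn_runconfig`.
#' @param plots Render per-readout PNG figures.
#' @return Invisibly, a list with `models`, `runs`, `table`, `checks` and
#'   `all_pass` (logical).
#' @export
run_reproduce <- function(config = run_config(), plots = FALSE) {
  built <- run_build(config)
  runs <- list()
  for (sc in names(built$models))
    runs[[sc]] <- simulate(built$models[[sc]], settings = config$settings)
  for (sc in names(runs))
    write_timecourse_csv(runs[[sc]],
                         file.path(config$out_dir, paste0(sc, "_timecourse.csv")))
  cmp <- run_compare(config, runs = runs)
  if (plots) {
    for (rd in config$readouts) {
      grDevices::png(file.path(config$out_dir, paste0(rd, ".png")),
                     width = 700, height = 500)
      plot_readout_comparison(runs, rd)
      grDevices::dev.off()
    }
  }
  all_pass <- all(cmp$checks$pass, na.rm = TRUE)
  invisible(list(models = built$models, runs = runs, table = cmp$table,
                 checks = cmp$checks, all_pass = all_pass))
}
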