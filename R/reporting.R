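# Command entry points: configuration in, CSV/JSON out, each run
# accompanied by a manifest. Log messages go to the message stream, never
# into data files.

.pkg_version <- function() as.character(utils::packageVersion("pecost"))

#' Run manifest
#'
#' Provenance record written next to every command output: command name,
#' MD5 digest of the configuration file, seed (if any), package version
#' and timestamp. Deterministic outputs are pure functions of the
#' manifest minus its timestamp.
#'
#' @param command Command name.
#' @param config_path Path to the configuration file used.
#' @param seed Integer seed, or `NULL` for deterministic commands.
#' @return A `run_manifest` object (list).
#' @export
run_manifest <- function(command, config_path, seed = NULL) {
  stopifnot(is.character(command), length(command) == 1L)
  digest <- if (!is.null(config_path) && file.exists(config_path)) {
    unname(tools::md5sum(config_path))
  } else NA_character_
  structure(list(
    command = command,
    config_digest = digest,
    seed = if (is.null(seed)) NULL else as.integer(seed),
    package_version = .pkg_version(),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "run_manifest")
}

.write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(unclass(manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(NULL)
}

.ensure_dir <- function(out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  out_dir
}

# Resolve a configuration into a calibrated parameter bundle. When the
# config leaves nicu_days unset, calibration runs automatically against
# the config's calibration_target (or the package default) and the
# calibrated value is logged; an explicit nicu_days suppresses calibration.
.load_calibrated <- function(config_path) {
  params <- read_config(config_path)
  target <- attr(params, "calibration_target")
  if (is.null(target)) target <- default_calibration_target()
  calibrated <- NA_real_
  if (is.na(params$stays$nicu_days)) {
    calibrated <- calibrate_nicu_days(params, target)
    params <- set_nicu_days(params, calibrated)
    message(sprintf(
      "calibrated NICU length of stay: %.4f days (target saving %.4f JPY)",
      calibrated, target))
  }
  attr(params, "calibrated_nicu_days") <- calibrated
  params
}

#' Base-case command: evaluate both scenarios and the saving
#'
#' Reads a configuration, calibrates the NICU stay if it is unset, and
#' writes `base_case_breakdown.csv` (per-component cohort costs of both
#' scenarios), `base_case_saving.json` and `manifest.json` to `out_dir`.
#'
#' @param config_path Path to a JSON configuration
#'   ([read_config()] format).
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the two `cost_breakdown`s, the
#'   `saving_result` and the parameter bundle.
#' @export
cmd_base_case <- function(config_path, out_dir = ".") {
  .ensure_dir(out_dir)
  params <- .load_calibrated(config_path)
  saving <- per_patient_saving(params)
  write_breakdown_csv(breakdown_df(saving$no_test, saving$test),
                      file.path(out_dir, "base_case_breakdown.csv"))
  write_saving_json(saving, file.path(out_dir, "base_case_saving.json"))
  .write_manifest(run_manifest("base-case", config_path), out_dir)
  message(sprintf("per-patient saving: %s JPY; budget impact: %s JPY",
                  format(round(saving$per_patient_saving), big.mark = ","),
                  format(round(saving$budget_impact), big.mark = ",")))
  invisible(list(no_test = saving$no_test, test = saving$test,
                 saving = saving, params = params))
}

#' Sensitivity command: run scenarios and tabulate
#'
#' Runs the built-in published scenarios, or scenarios read from a JSON
#' file, and writes `sensitivity.csv` (Table-2 style columns),
#' `sensitivity.json` (rows plus per-component deltas) and
#' `manifest.json`.
#'
#' @inheritParams cmd_base_case
#' @param scenarios_path Path to a JSON scenario file
#'   ([read_scenarios()] format), or `NULL`.
#' @param builtin Use [builtin_scenarios()]; default when
#'   `scenarios_path` is `NULL`.
#' @return Invisibly, the `sensitivity_table`.
#' @export
cmd_sensitivity <- function(config_path, scenarios_path = NULL,
                            builtin = is.null(scenarios_path),
                            out_dir = ".") {
  .ensure_dir(out_dir)
  params <- .load_calibrated(config_path)
  specs <- if (!is.null(scenarios_path)) read_scenarios(scenarios_path)
           else if (builtin) builtin_scenarios()
           else list()
  tab <- run_sensitivity(specs, params)
  out <- as.data.frame(tab)
  out$saving_jpy <- round(out$saving_jpy)  # plain integers in CSV
  utils::write.csv(out, file.path(out_dir, "sensitivity.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(rows = as.data.frame(tab), component_deltas = attr(tab, "deltas")),
    file.path(out_dir, "sensitivity.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null",
    null = "null")
  .write_manifest(run_manifest("sensitivity", config_path), out_dir)
  invisible(tab)
}

#' Simulation command: cohort CSVs and analytic-vs-Monte-Carlo report
#'
#' Simulates a no-test and a test cohort of `n` women, writes them as
#' `cohort_no_test.csv` / `cohort_test.csv`, and writes
#' `simulation_report.json` comparing the analytic per-patient cost of
#' each scenario (and the saving) against its Monte Carlo estimate. A
#' comparison is flagged `PASS` when the absolute difference is within 3
#' standard errors, `SE_UNDEFINED` when n = 1.
#'
#' @inheritParams cmd_base_case
#' @param n Number of women per cohort (>= 1).
#' @param seed Integer seed (the no-test cohort uses `seed + 1`).
#' @return Invisibly, the report list.
#' @export
cmd_simulate <- function(config_path, n, seed = 1L, out_dir = ".") {
  .ensure_dir(out_dir)
  params <- .load_calibrated(config_path)
  cfg <- sim_config(n, seed)
  coh_test <- simulate_cohort(cfg, params, "test")
  coh_no <- simulate_cohort(sim_config(cfg$n_women, cfg$seed + 1L),
                            params, "no_test")
  write_cohort_csv(coh_no, file.path(out_dir, "cohort_no_test.csv"))
  write_cohort_csv(coh_test, file.path(out_dir, "cohort_test.csv"))

  compare <- function(analytic, mc) {
    flag <- if (is.na(mc$se)) "SE_UNDEFINED"
            else if (abs(analytic - mc$mean) < 3 * mc$se) "PASS"
            else "FAIL"
    list(analytic = analytic, monte_carlo = mc$mean, se = mc$se,
         abs_difference = abs(analytic - mc$mean), flag = flag)
  }
  mc_no <- monte_carlo_cost(coh_no, params$costs)
  mc_test <- monte_carlo_cost(coh_test, params$costs)
  saving <- per_patient_saving(params)
  mc_saving <- list(mean = mc_no$mean - mc_test$mean,
                    se = sqrt(mc_no$se^2 + mc_test$se^2))
  report <- list(
    n = cfg$n_women, seed = cfg$seed,
    per_patient_cost = list(
      no_test = compare(saving$no_test$per_patient, mc_no),
      test = compare(saving$test$per_patient, mc_test)
    ),
    per_patient_saving = compare(saving$per_patient_saving, mc_saving)
  )
  jsonlite::write_json(report, file.path(out_dir, "simulation_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  .write_manifest(run_manifest("simulate", config_path, seed = cfg$seed),
                  out_dir)
  invisible(report)
}

#' Calibration command
#'
#' Calibrates the NICU length of stay against the configuration's target
#' (or the package default) and writes `calibration.json`.
#'
#' @inheritParams cmd_base_case
#' @return Invisibly, the calibrated NICU days.
#' @export
cmd_calibrate <- function(config_path, out_dir = ".") {
  .ensure_dir(out_dir)
  params <- read_config(config_path)
  target <- attr(params, "calibration_target")
  if (is.null(target)) target <- default_calibration_target()
  days <- calibrate_nicu_days(params, target)
  check <- per_patient_saving(set_nicu_days(params, days))
  jsonlite::write_json(list(
    nicu_days = days,
    target_saving_jpy = target,
    achieved_saving_jpy = check$per_patient_saving
  ), file.path(out_dir, "calibration.json"),
  auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .write_manifest(run_manifest("calibrate", config_path), out_dir)
  message(sprintf("calibrated NICU length of stay: %.4f days", days))
  invisible(days)
}

#' Path to the packaged default configuration
#'
#' A configuration reproducing the published base case: exact-fraction
#' branch probabilities, published unit costs and stays, and an
#' uncalibrated NICU stay (resolved at run time by calibration).
#'
#' @return File path.
#' @export
default_config_path <- function() {
  system.file("extdata", "default_config.json", package = "pecost",
              mustWork = TRUE)
}
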