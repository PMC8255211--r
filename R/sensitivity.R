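# One-way sensitivity scenarios over the analytic model.

#' Define a sensitivity scenario
#'
#' A scenario is a named set of parameter overrides applied to a fresh
#' copy of the base parameters. Override paths are dotted,
#' `"<block>.<field>"`, with blocks `probs`, `costs`, `stays`, `neonatal`,
#' `cohort`, `performance`, or the top-level scalar `"pe_incidence"`.
#'
#' @param name Scenario label.
#' @param overrides Named list of `path = value` pairs (may be empty).
#' @param retest `NA` to inherit the base retest flag, otherwise a
#'   logical.
#' @param approximate Mark scenarios whose published result the model
#'   structure is known not to reproduce exactly; carried into output
#'   metadata.
#' @return A `scenario_spec` object.
#' @export
scenario_spec <- function(name, overrides = list(), retest = NA,
                          approximate = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.list(overrides),
            length(retest) == 1L, is.logical(retest) || is.na(retest),
            is.logical(approximate), length(approximate) == 1L)
  if (length(overrides) &&
      (is.null(names(overrides)) || any(!nzchar(names(overrides))))) {
    stop("every override must be named by a parameter path", call. = FALSE)
  }
  structure(list(name = name, overrides = overrides,
                 retest = as.logical(retest),
                 approximate = isTRUE(approximate)),
            class = "scenario_spec")
}

.is_base_spec <- function(spec) {
  length(spec$overrides) == 0L && (is.na(spec$retest) || !spec$retest)
}

# Blocks whose fields may be overridden, with their re-validating
# constructors.
.override_blocks <- list(
  probs = decision_tree_probabilities,
  costs = cost_inputs,
  stays = stay_durations,
  neonatal = neonatal_assumptions,
  cohort = model_cohort,
  performance = clinical_performance
)

#' Apply scenario overrides to a parameter bundle
#'
#' Returns a new bundle with the overridden fields replaced and the
#' affected parameter block re-validated; the input bundle is untouched.
#' Unknown paths error, naming the offending path.
#'
#' @param params A [pe_parameters()] bundle.
#' @param spec A [scenario_spec()].
#' @return A new `pe_params` bundle.
#' @export
apply_scenario <- function(params, spec) {
  stopifnot(inherits(params, "pe_params"), inherits(spec, "scenario_spec"))
  out <- params
  for (path in names(spec$overrides)) {
    value <- spec$overrides[[path]]
    if (identical(path, "pe_incidence")) {
      out$pe_incidence <- .check_prob(value, "pe_incidence")
      next
    }
    parts <- strsplit(path, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !parts[1] %in% names(.override_blocks)) {
      stop(sprintf("unknown parameter path '%s'", path), call. = FALSE)
    }
    block <- parts[1]; field <- parts[2]
    ctor <- .override_blocks[[block]]
    if (!field %in% names(formals(ctor))) {
      stop(sprintf("unknown parameter path '%s': no field '%s' in '%s'",
                   path, field, block), call. = FALSE)
    }
    fields <- unclass(out[[block]])
    attributes(fields) <- list(names = names(fields))
    fields[[field]] <- value
    out[[block]] <- do.call(ctor, fields)  # re-validates the whole block
  }
  if (!is.na(spec$retest)) out$retest <- spec$retest
  out
}

#' The eight published one-way scenarios
#'
#' Base case plus the seven published variations: the no-test admission
#' rate raised to the 26.9% observed across all of PROGNOSIS Asia; the
#' test cost varied by ±20% (7,200 / 10,800 JPY); a second test for every
#' woman; the low-stratum admission rate raised to 4% and lowered to 0%;
#' and the high-stratum admission rate raised by 10 percentage points to
#' 50%. The 26.9% scenario is flagged `approximate`: its published saving
#' is not reproducible from the model structure and main-text parameters
#' (see the methods vignette).
#'
#' @return A list of 8 [scenario_spec()] objects, base case first.
#' @export
builtin_scenarios <- function() {
  list(
    scenario_spec("base_case"),
    scenario_spec("no_test_rate_26.9pct",
                  list("probs.p_hosp_no_test" = 0.269), approximate = TRUE),
    scenario_spec("test_cost_minus_20pct", list("costs.test_cost" = 7200)),
    scenario_spec("test_cost_plus_20pct", list("costs.test_cost" = 10800)),
    scenario_spec("retest_every_woman", retest = TRUE),
    scenario_spec("p_hosp_low_4pct", list("probs.p_hosp_given_low" = 0.04)),
    scenario_spec("p_hosp_low_0pct", list("probs.p_hosp_given_low" = 0)),
    scenario_spec("p_hosp_high_50pct", list("probs.p_hosp_given_high" = 0.50))
  )
}

#' Run one-way sensitivity scenarios
#'
#' Evaluates [per_patient_saving()] for each scenario against a fresh
#' copy of the base parameters (no leakage between rows). The base case
#' is always row 1: if the first spec is not a base spec, a `base_case`
#' row is prepended. A row whose overrides fail validation records the
#' error and leaves its saving `NA`; the remaining rows still run.
#'
#' @param specs List of [scenario_spec()] objects (may be empty).
#' @param params Calibrated base [pe_parameters()] bundle.
#' @return A `sensitivity_table` (data.frame): scenario name, the Table-2
#'   style parameter columns (`p_hosp_no_test`, `test_cost_jpy`, `retest`,
#'   `p_hosp_given_low`, `p_hosp_given_high`), `saving_jpy`,
#'   `approximate`, `error`. Per-scenario component deltas are in the
#'   `"deltas"` attribute.
#' @export
run_sensitivity <- function(specs = builtin_scenarios(), params = NULL) {
  if (is.null(params)) {
    params <- set_nicu_days(pe_parameters(),
                            calibrate_nicu_days(pe_parameters()))
  }
  stopifnot(inherits(params, "pe_params"), is.list(specs),
            all(vapply(specs, inherits, logical(1), "scenario_spec")))
  if (length(specs) == 0L || !.is_base_spec(specs[[1]])) {
    specs <- c(list(scenario_spec("base_case")), specs)
  }
  rows <- lapply(specs, function(spec) {
    res <- tryCatch({
      pars <- apply_scenario(params, spec)
      sv <- per_patient_saving(pars)
      list(pars = pars, saving = sv$per_patient_saving,
           deltas = sv$component_deltas, error = NA_character_)
    }, error = function(e) {
      list(pars = params, saving = NA_real_, deltas = NULL,
           error = conditionMessage(e))
    })
    data.frame(
      scenario = spec$name,
      p_hosp_no_test = res$pars$probs$p_hosp_no_test,
      test_cost_jpy = res$pars$costs$test_cost,
      retest = res$pars$retest,
      p_hosp_given_low = res$pars$probs$p_hosp_given_low,
      p_hosp_given_high = res$pars$probs$p_hosp_given_high,
      saving_jpy = res$saving,
      approximate = spec$approximate,
      error = res$error,
      row.names = NULL
    )
  })
  tab <- do.call(rbind, rows)
  attr(tab, "deltas") <- stats::setNames(
    lapply(seq_along(specs), function(i) {
      d <- tryCatch(per_patient_saving(
        apply_scenario(params, specs[[i]]))$component_deltas,
        error = function(e) NULL)
      if (is.null(d)) NULL else as.list(d)
    }), tab$scenario)
  class(tab) <- c("sensitivity_table", "data.frame")
  tab
}

#' @export
print.sensitivity_table <- function(x, ...) {
  cat("One-way sensitivity analysis (per-patient saving, JPY)\n")
  df <- as.data.frame(x)
  df$saving_jpy <- round(df$saving_jpy)
  df$p_hosp_no_test <- round(100 * df$p_hosp_no_test, 1)
  df$p_hosp_given_low <- round(100 * df$p_hosp_given_low, 2)
  df$p_hosp_given_high <- round(100 * df$p_hosp_given_high, 1)
  names(df)[names(df) == "p_hosp_no_test"] <- "no_test_rate_pct"
  names(df)[names(df) == "p_hosp_given_low"] <- "low_rate_pct"
  names(df)[names(df) == "p_hosp_given_high"] <- "high_rate_pct"
  print(df[, c("scenario", "no_test_rate_pct", "test_cost_jpy", "retest",
               "low_rate_pct", "high_rate_pct", "saving_jpy")],
        row.names = FALSE)
  if (any(x$approximate)) {
    cat("scenarios flagged approximate:",
        paste(x$scenario[x$approximate], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tornado ordering of sensitivity rows
#'
#' Orders the non-base rows by the absolute excursion of their saving
#' from the base-case saving, largest first; ties keep their original
#' order. Rows with failed runs (`NA` saving) sort last.
#'
#' @param table A `sensitivity_table` from [run_sensitivity()].
#' @return The non-base rows, reordered, with a `delta_jpy` column
#'   (saving minus base saving) added.
#' @export
tornado_ranking <- function(table) {
  stopifnot(inherits(table, "sensitivity_table"), nrow(table) >= 1L)
  base_saving <- table$saving_jpy[1]
  rest <- as.data.frame(table)[-1, , drop = FALSE]
  if (nrow(rest) == 0L) return(rest)
  rest$delta_jpy <- rest$saving_jpy - base_saving
  ord <- order(-abs(rest$delta_jpy), seq_len(nrow(rest)), na.last = TRUE)
  out <- rest[ord, , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Read scenario specs from a JSON file
#'
#' The file holds an array of objects with keys `name`, `overrides`
#' (object mapping parameter paths to values), and optional `retest`,
#' `approximate`.
#'
#' @param path Path to the JSON scenario file.
#' @return List of [scenario_spec()] objects.
#' @export
read_scenarios <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("scenario file not found: '%s'", path), call. = FALSE)
  }
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(x) {
    scenario_spec(
      name = x$name,
      overrides = if (is.null(x$overrides)) list() else x$overrides,
      retest = if (is.null(x$retest)) NA else x$retest,
      approximate = isTRUE(x$approximate)
    )
  })
}
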