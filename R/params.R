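# Parameter containers for the two-scenario preeclampsia triage cost model.
# Each constructor validates its fields; invalid input errors name the field.

.check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single probability in [0, 1] (got %s)",
                 field, format(x)), call. = FALSE)
  }
  as.numeric(x)
}

.check_nonneg <- function(x, field, allow_na = FALSE) {
  if (allow_na && length(x) == 1L && is.na(x)) return(NA_real_)
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
    stop(sprintf("'%s' must be a single non-negative number (got %s)",
                 field, format(x)), call. = FALSE)
  }
  as.numeric(x)
}

#' Decision-tree branch probabilities
#'
#' Hospitalization probabilities of the no-test and test pathways for women
#' presenting with suspected preeclampsia. Under standard care a fraction
#' `p_hosp_no_test` is admitted on suspicion. When the sFlt-1/PlGF ratio is
#' added, women split at the cutoff of 38 into a low-risk stratum
#' (`share_low`, ratio <= 38) admitted with probability `p_hosp_given_low`
#' and a high-risk stratum (`share_high`) admitted with probability
#' `p_hosp_given_high`.
#'
#' Defaults are the exact Japanese-cohort fractions (26/180 hospitalized,
#' 143/180 at or below the cutoff) rather than their rounded percentage
#' forms. The default high-stratum admission probability is the
#' conservative planning value 0.40; the observed cohort value 0.27 is
#' kept as the `observed_p_hosp_given_high` attribute for reference and is
#' not used in computation.
#'
#' @param p_hosp_no_test Probability of admission under standard care.
#' @param share_low,share_high Fractions with ratio <= 38 and > 38; must
#'   sum to 1 within 1e-9.
#' @param p_hosp_given_low,p_hosp_given_high Admission probabilities within
#'   the low and high strata.
#' @return An object of class `dt_probs`.
#' @examples
#' p <- decision_tree_probabilities()
#' overall_test_hosp_rate(p)
#' @export
decision_tree_probabilities <- function(p_hosp_no_test = 26 / 180,
                                        share_low = 143 / 180,
                                        share_high = 37 / 180,
                                        p_hosp_given_low = 0.0056,
                                        p_hosp_given_high = 0.40) {
  out <- list(
    p_hosp_no_test    = .check_prob(p_hosp_no_test, "p_hosp_no_test"),
    share_low         = .check_prob(share_low, "share_low"),
    share_high        = .check_prob(share_high, "share_high"),
    p_hosp_given_low  = .check_prob(p_hosp_given_low, "p_hosp_given_low"),
    p_hosp_given_high = .check_prob(p_hosp_given_high, "p_hosp_given_high")
  )
  if (abs(out$share_low + out$share_high - 1) > 1e-9) {
    stop("'share_low' and 'share_high' must sum to 1 (tolerance 1e-9)",
         call. = FALSE)
  }
  attr(out, "observed_p_hosp_given_high") <- 0.27
  structure(out, class = "dt_probs")
}

#' Unit costs (JPY)
#'
#' The five unit costs of the model, in Japanese yen: routine outpatient
#' care per woman, maternal hospitalization per inpatient day, the
#' sFlt-1/PlGF ratio test, a course of maternal corticosteroids, and one
#' NICU day. Defaults are Ministry of Health, Labour and Welfare figures.
#'
#' @param outpatient Outpatient care per woman.
#' @param hosp_per_day Maternal hospitalization, per day.
#' @param test_cost One sFlt-1/PlGF ratio test.
#' @param corticosteroid Corticosteroid course per admitted woman.
#' @param nicu_per_day NICU stay, per day.
#' @return An object of class `cost_inputs`.
#' @export
cost_inputs <- function(outpatient = 57053,
                        hosp_per_day = 87300,
                        test_cost = 9000,
                        corticosteroid = 1752,
                        nicu_per_day = 101302) {
  out <- list(
    outpatient     = .check_nonneg(outpatient, "outpatient"),
    hosp_per_day   = .check_nonneg(hosp_per_day, "hosp_per_day"),
    test_cost      = .check_nonneg(test_cost, "test_cost"),
    corticosteroid = .check_nonneg(corticosteroid, "corticosteroid"),
    nicu_per_day   = .check_nonneg(nicu_per_day, "nicu_per_day")
  )
  structure(out, class = "cost_inputs")
}

#' Lengths of stay (days)
#'
#' Stay durations entering the cost arithmetic: the pre-onset admission on
#' suspicion of preeclampsia (4 days), the birth-period stay with (13.6)
#' and without (9.3) preeclampsia, and the NICU stay per respiratory
#' distress syndrome (RDS) admission. The NICU length of stay is the one
#' parameter not published; it defaults to `NA` and is resolved by
#' [calibrate_nicu_days()]. `avg_los_no_test` / `avg_los_test` are the
#' reported scenario-average stays, carried only for the
#' [check_los_consistency()] diagnostic.
#'
#' @param pre_onset_days Pre-onset admission length.
#' @param birth_pe_days,birth_no_pe_days Birth-period stay with/without
#'   preeclampsia; the former must not be shorter.
#' @param avg_los_no_test,avg_los_test Reported scenario averages
#'   (diagnostic only).
#' @param nicu_days NICU stay per RDS admission; `NA` until calibrated.
#' @return An object of class `stay_durations`.
#' @export
stay_durations <- function(pre_onset_days = 4,
                           birth_pe_days = 13.6,
                           birth_no_pe_days = 9.3,
                           avg_los_no_test = 10.4,
                           avg_los_test = 10.2,
                           nicu_days = NA_real_) {
  out <- list(
    pre_onset_days   = .check_nonneg(pre_onset_days, "pre_onset_days"),
    birth_pe_days    = .check_nonneg(birth_pe_days, "birth_pe_days"),
    birth_no_pe_days = .check_nonneg(birth_no_pe_days, "birth_no_pe_days"),
    avg_los_no_test  = .check_nonneg(avg_los_no_test, "avg_los_no_test"),
    avg_los_test     = .check_nonneg(avg_los_test, "avg_los_test"),
    nicu_days        = .check_nonneg(nicu_days, "nicu_days", allow_na = TRUE)
  )
  if (out$birth_pe_days < out$birth_no_pe_days) {
    stop("'birth_pe_days' must be >= 'birth_no_pe_days'", call. = FALSE)
  }
  structure(out, class = "stay_durations")
}

#' Neonatal assumptions
#'
#' RDS risk in neonates of mothers hospitalized with suspected
#' preeclampsia (12%), and the relative reduction of that risk when
#' admission is guided by the sFlt-1/PlGF ratio with corticosteroid cover
#' (20%; the 25.6% reduction reported upstream at the lower cutoff of 33
#' is kept as the `reported_rds_reduction` attribute). Every RDS neonate
#' is assumed admitted to the NICU.
#'
#' @param rds_rate RDS probability for neonates of hospitalized mothers.
#' @param rds_reduction Relative reduction of `rds_rate` in the test
#'   scenario.
#' @return An object of class `neonatal_assumptions`.
#' @export
neonatal_assumptions <- function(rds_rate = 0.12, rds_reduction = 0.20) {
  out <- list(
    rds_rate      = .check_prob(rds_rate, "rds_rate"),
    rds_reduction = .check_prob(rds_reduction, "rds_reduction")
  )
  attr(out, "reported_rds_reduction") <- 0.256
  structure(out, class = "neonatal_assumptions")
}

#' Cohort sizes
#'
#' `n_model` is the modelled population: 31,000 women with suspected
#' preeclampsia in Japan at any given time. `n_sample` (180) and
#' `n_enrolled` (192) record the Japanese analysis cohort the branch
#' probabilities come from.
#'
#' @param n_model Modelled cohort size (> 0).
#' @param n_sample Analysis-set size of the source cohort.
#' @param n_enrolled Enrolled size of the source cohort (>= `n_sample`).
#' @return An object of class `model_cohort`.
#' @export
model_cohort <- function(n_model = 31000, n_sample = 180, n_enrolled = 192) {
  out <- list(
    n_model    = .check_nonneg(n_model, "n_model"),
    n_sample   = .check_nonneg(n_sample, "n_sample"),
    n_enrolled = .check_nonneg(n_enrolled, "n_enrolled")
  )
  if (out$n_sample > out$n_enrolled) {
    stop("'n_sample' must be <= 'n_enrolled'", call. = FALSE)
  }
  structure(out, class = "model_cohort")
}

#' Clinical performance of the ratio cutoff
#'
#' Predictive values of the sFlt-1/PlGF ratio at the cutoff of 38 in the
#' Japanese cohort: negative predictive value for ruling out preeclampsia
#' within 1 and 4 weeks, and positive predictive value for ruling it in.
#' These are consumed as constants by the cohort simulator; the package
#' does not re-estimate them.
#'
#' @param cutoff Ratio threshold separating low from high risk.
#' @param npv_1wk,npv_4wk Negative predictive values at 1 and 4 weeks
#'   (`npv_1wk >= npv_4wk`).
#' @param ppv_1wk,ppv_4wk Positive predictive values at 1 and 4 weeks
#'   (`ppv_1wk <= ppv_4wk`).
#' @return An object of class `clinical_performance`.
#' @export
clinical_performance <- function(cutoff = 38,
                                 npv_1wk = 0.986, npv_4wk = 0.951,
                                 ppv_1wk = 0.179, ppv_4wk = 0.303) {
  out <- list(
    cutoff  = .check_nonneg(cutoff, "cutoff"),
    npv_1wk = .check_prob(npv_1wk, "npv_1wk"),
    npv_4wk = .check_prob(npv_4wk, "npv_4wk"),
    ppv_1wk = .check_prob(ppv_1wk, "ppv_1wk"),
    ppv_4wk = .check_prob(ppv_4wk, "ppv_4wk")
  )
  if (out$npv_1wk < out$npv_4wk) {
    stop("'npv_1wk' must be >= 'npv_4wk'", call. = FALSE)
  }
  if (out$ppv_1wk > out$ppv_4wk) {
    stop("'ppv_1wk' must be <= 'ppv_4wk'", call. = FALSE)
  }
  structure(out, class = "clinical_performance")
}

#' Preeclampsia incidence implied by the stratum predictive values
#'
#' The birth-episode cost component needs an overall preeclampsia
#' incidence. The model takes it as the cutoff-stratified mixture
#' `share_low * (1 - npv_4wk) + share_high * ppv_4wk`, so that the
#' analytic birth component equals the expectation of the cohort
#' simulator, which draws 4-week preeclampsia from exactly these stratum
#' risks. Incidence is scenario-independent, so this component cancels in
#' every saving.
#'
#' @param probs A [decision_tree_probabilities()] object.
#' @param performance A [clinical_performance()] object.
#' @return Implied 4-week preeclampsia incidence (probability).
#' @export
implied_pe_incidence <- function(probs = decision_tree_probabilities(),
                                 performance = clinical_performance()) {
  stopifnot(inherits(probs, "dt_probs"),
            inherits(performance, "clinical_performance"))
  probs$share_low * (1 - performance$npv_4wk) +
    probs$share_high * performance$ppv_4wk
}

#' Bundle of all model parameters
#'
#' Collects the typed parameter blocks into a single object consumed by
#' the model, the sensitivity engine and the simulator. `pe_incidence`
#' defaults to [implied_pe_incidence()]; `retest` indicates whether every
#' woman receives a second ratio test.
#'
#' @param probs [decision_tree_probabilities()] object.
#' @param costs [cost_inputs()] object.
#' @param stays [stay_durations()] object.
#' @param neonatal [neonatal_assumptions()] object.
#' @param cohort [model_cohort()] object.
#' @param performance [clinical_performance()] object.
#' @param pe_incidence Overall 4-week preeclampsia incidence; `NULL` means
#'   derive it from `probs` and `performance`.
#' @param retest Logical; charge the test twice per woman in the test
#'   scenario.
#' @return An object of class `pe_params`.
#' @examples
#' pars <- pe_parameters()
#' pars <- set_nicu_days(pars, calibrate_nicu_days(pars))
#' per_patient_saving(pars)
#' @export
pe_parameters <- function(probs = decision_tree_probabilities(),
                          costs = cost_inputs(),
                          stays = stay_durations(),
                          neonatal = neonatal_assumptions(),
                          cohort = model_cohort(),
                          performance = clinical_performance(),
                          pe_incidence = NULL,
                          retest = FALSE) {
  stopifnot(inherits(probs, "dt_probs"), inherits(costs, "cost_inputs"),
            inherits(stays, "stay_durations"),
            inherits(neonatal, "neonatal_assumptions"),
            inherits(cohort, "model_cohort"),
            inherits(performance, "clinical_performance"),
            is.logical(retest), length(retest) == 1L, !is.na(retest))
  if (is.null(pe_incidence)) {
    pe_incidence <- implied_pe_incidence(probs, performance)
  }
  structure(list(
    probs = probs, costs = costs, stays = stays, neonatal = neonatal,
    cohort = cohort, performance = performance,
    pe_incidence = .check_prob(pe_incidence, "pe_incidence"),
    retest = retest
  ), class = "pe_params")
}

#' Set the NICU length of stay on a parameter bundle
#'
#' @param params A [pe_parameters()] bundle.
#' @param nicu_days NICU stay per RDS admission, in days.
#' @return The bundle with `stays$nicu_days` replaced.
#' @export
set_nicu_days <- function(params, nicu_days) {
  stopifnot(inherits(params, "pe_params"))
  params$stays$nicu_days <- .check_nonneg(nicu_days, "nicu_days")
  params
}

#' @export
print.pe_params <- function(x, ...) {
  cat("Preeclampsia triage cost-model parameters\n")
  cat(sprintf("  cohort: n_model = %s (source cohort %d/%d)\n",
              format(x$cohort$n_model, big.mark = ","),
              x$cohort$n_sample, x$cohort$n_enrolled))
  cat(sprintf("  no-test admission rate: %.4f\n", x$probs$p_hosp_no_test))
  cat(sprintf("  ratio <=38: %.4f (admit %.4f) | >38: %.4f (admit %.2f)\n",
              x$probs$share_low, x$probs$p_hosp_given_low,
              x$probs$share_high, x$probs$p_hosp_given_high))
  cat(sprintf("  RDS: %.2f, reduced by %.2f under testing\n",
              x$neonatal$rds_rate, x$neonatal$rds_reduction))
  nd <- x$stays$nicu_days
  cat(sprintf("  NICU stay: %s days%s\n",
              if (is.na(nd)) "uncalibrated" else format(round(nd, 3)),
              if (x$retest) " | retest: yes" else ""))
  invisible(x)
}

# --- configuration file IO ---------------------------------------------------

#' Read model parameters from a JSON configuration file
#'
#' The file mirrors the parameter blocks: top-level keys `probabilities`,
#' `costs`, `stays`, `neonatal`, `cohort`, `performance`, plus optional
#' scalars `pe_incidence`, `retest` and `calibration_target`. Missing keys
#' fall back to the package defaults; every supplied value passes the same
#' validation as the constructors. A `null` (or absent) `stays.nicu_days`
#' marks the NICU length of stay as uncalibrated. The packaged default
#' configuration is at `system.file("extdata", "default_config.json",
#' package = "pecost")`.
#'
#' @param path Path to a JSON configuration file.
#' @return A [pe_parameters()] bundle, with attribute `calibration_target`
#'   (the per-patient saving the NICU stay should be calibrated to;
#'   `NULL` means use [default_calibration_target()]).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("configuration file not found: '%s'", path), call. = FALSE)
  }
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("probabilities", "costs", "stays", "neonatal", "cohort",
             "performance", "pe_incidence", "retest", "calibration_target")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    stop(sprintf("unknown configuration key(s): %s",
                 paste(sQuote(bad), collapse = ", ")), call. = FALSE)
  }
  build <- function(ctor, block, allowed) {
    vals <- cfg[[block]]
    if (is.null(vals)) return(ctor())
    vals <- vals[!vapply(vals, is.null, logical(1))]
    bad <- setdiff(names(vals), allowed)
    if (length(bad)) {
      stop(sprintf("unknown key(s) in '%s': %s", block,
                   paste(sQuote(bad), collapse = ", ")), call. = FALSE)
    }
    do.call(ctor, vals)
  }
  params <- pe_parameters(
    probs = build(decision_tree_probabilities, "probabilities",
                  names(formals(decision_tree_probabilities))),
    costs = build(cost_inputs, "costs", names(formals(cost_inputs))),
    stays = build(stay_durations, "stays", names(formals(stay_durations))),
    neonatal = build(neonatal_assumptions, "neonatal",
                     names(formals(neonatal_assumptions))),
    cohort = build(model_cohort, "cohort", names(formals(model_cohort))),
    performance = build(clinical_performance, "performance",
                        names(formals(clinical_performance))),
    pe_incidence = cfg$pe_incidence,
    retest = isTRUE(cfg$retest)
  )
  attr(params, "calibration_target") <- cfg$calibration_target
  params
}

#' Write model parameters to a JSON configuration file
#'
#' @param params A [pe_parameters()] bundle.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path) {
  stopifnot(inherits(params, "pe_params"))
  cfg <- list(
    probabilities = unclass(params$probs),
    costs = unclass(params$costs),
    stays = unclass(params$stays),
    neonatal = unclass(params$neonatal),
    cohort = unclass(params$cohort),
    performance = unclass(params$performance),
    pe_incidence = params$pe_incidence,
    retest = params$retest
  )
  attributes(cfg$probabilities) <- list(names = names(cfg$probabilities))
  attributes(cfg$neonatal) <- list(names = names(cfg$neonatal))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
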