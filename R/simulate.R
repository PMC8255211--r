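# Patient-level synthetic cohorts with the statistical structure the
# analytic model assumes; Monte Carlo oracle for its expectations.
#
# No patient-level ratio distribution is published: the ratio draw is a
# two-component truncated-lognormal mixture whose only contract is the
# (share_low, share_high) split at the cutoff. Its shape parameters are
# arbitrary and never touch any cost.

.ratio_shape <- list(low = c(meanlog = log(14), sdlog = 0.8),
                     high = c(meanlog = log(85), sdlog = 0.6))

# Stay draws: gamma with fixed coefficient of variation; only the mean
# enters the analytic model.
.stay_cv <- 0.5

.rstay <- function(n, mean_days, cv = .stay_cv) {
  if (mean_days == 0) return(rep(0, n))
  shape <- 1 / cv^2
  stats::rgamma(n, shape = shape, rate = shape / mean_days)
}

# Truncated lognormal: low stratum on (0, cutoff], high on (cutoff, Inf).
.rratio <- function(u, stratum, cutoff) {
  p <- .ratio_shape[[stratum]]
  f_cut <- stats::plnorm(cutoff, p[["meanlog"]], p[["sdlog"]])
  q <- if (stratum == "low") u * f_cut else f_cut + u * (1 - f_cut)
  stats::qlnorm(q, p[["meanlog"]], p[["sdlog"]])
}

#' Simulation configuration
#'
#' @param n_women Number of women to simulate (>= 1).
#' @param seed Integer RNG seed; the same seed yields a byte-identical
#'   cohort.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_women, seed = 1L) {
  n_women <- .check_nonneg(n_women, "n_women")
  if (n_women < 1 || n_women != round(n_women)) {
    stop("'n_women' must be a positive integer", call. = FALSE)
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  structure(list(n_women = as.integer(n_women), seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a patient-level cohort
#'
#' Draws one woman-plus-neonate trajectory per row, realizing the
#' decision-tree branches:
#' * `sflt_plgf_ratio` from a positive two-component mixture straddling
#'   the cutoff, with stratum weights (`share_low`, `share_high`);
#' * `hosp_standard_care`: admission under standard surveillance,
#'   Bernoulli `p_hosp_no_test` — this latent flag defines the neonatal
#'   RDS risk pool in both scenarios, mirroring the model's accounting in
#'   which test-scenario NICU admissions are the standard-care admissions
#'   with the RDS rate reduced;
#' * `hospitalized_pre_onset`: the scenario's admission — the standard-care
#'   flag in the no-test scenario, stratum-specific Bernoullis
#'   (`p_hosp_given_low` / `p_hosp_given_high`) in the test scenario;
#' * 4-week preeclampsia from the stratum risks `1 - npv_4wk` (low) and
#'   `ppv_4wk` (high); 1-week preeclampsia nested within it;
#' * realized stays from positive (gamma) distributions with the
#'   configured means: pre-onset stay for admitted women, birth stay
#'   depending on preeclampsia, NICU stay for RDS neonates;
#' * `neonate_rds`: Bernoulli `rds_rate` within the standard-care
#'   admission pool, thinned by `rds_reduction` in the test scenario.
#'
#' @param cfg A [sim_config()].
#' @param params A [pe_parameters()] bundle; `stays$nicu_days` must be
#'   calibrated (non-`NA`).
#' @param scenario `"test"` (default) or `"no_test"`.
#' @return A data.frame, one row per woman, with attributes `scenario`,
#'   `retest` and `seed`.
#' @examples
#' pars <- set_nicu_days(pe_parameters(), 14.5)
#' coh <- simulate_cohort(sim_config(1000, seed = 7), pars)
#' mean(coh$stratum == "low")
#' @export
simulate_cohort <- function(cfg, params, scenario = "test") {
  stopifnot(inherits(cfg, "sim_config"), inherits(params, "pe_params"))
  scenario <- .match_scenario(scenario)
  if (is.na(params$stays$nicu_days)) {
    stop(paste("uncalibrated parameter: 'nicu_days' is NA;",
               "set it explicitly or via calibrate_nicu_days()"),
         call. = FALSE)
  }
  p <- params$probs; st <- params$stays; neo <- params$neonatal
  perf <- params$performance
  n <- cfg$n_women
  withr::with_seed(cfg$seed, {
    high <- stats::runif(n) < p$share_high
    stratum <- ifelse(high, "high", "low")
    u_ratio <- stats::runif(n)
    ratio <- numeric(n)
    ratio[!high] <- .rratio(u_ratio[!high], "low", perf$cutoff)
    ratio[high] <- .rratio(u_ratio[high], "high", perf$cutoff)

    hosp_std <- stats::runif(n) < p$p_hosp_no_test
    p_hosp_stratum <- ifelse(high, p$p_hosp_given_high, p$p_hosp_given_low)
    hosp_test <- stats::runif(n) < p_hosp_stratum
    hosp <- if (scenario == "no_test") hosp_std else hosp_test

    risk4 <- ifelse(high, perf$ppv_4wk, 1 - perf$npv_4wk)
    pe4 <- stats::runif(n) < risk4
    risk1 <- ifelse(high, perf$ppv_1wk, 1 - perf$npv_1wk)
    # nested: P(pe within 1wk | pe within 4wks) = risk1 / risk4
    cond1 <- ifelse(risk4 > 0, pmin(risk1 / risk4, 1), 0)
    pe1 <- pe4 & (stats::runif(n) < cond1)

    p_rds <- neo$rds_rate *
      (if (scenario == "test") 1 - neo$rds_reduction else 1)
    rds <- hosp_std & (stats::runif(n) < p_rds)

    pre_days <- .rstay(n, st$pre_onset_days) * hosp
    birth_draw_pe <- .rstay(n, st$birth_pe_days)
    birth_draw_no <- .rstay(n, st$birth_no_pe_days)
    birth_days <- ifelse(pe4, birth_draw_pe, birth_draw_no)
    nicu <- .rstay(n, st$nicu_days) * rds

    out <- data.frame(
      id = seq_len(n),
      sflt_plgf_ratio = ratio,
      stratum = stratum,
      hosp_standard_care = hosp_std,
      hospitalized_pre_onset = hosp,
      pe_within_1wk = pe1,
      pe_within_4wks = pe4,
      pre_onset_days = pre_days,
      birth_days = birth_days,
      neonate_rds = rds,
      nicu_days = nicu
    )
    attr(out, "scenario") <- scenario
    attr(out, "retest") <- params$retest
    attr(out, "seed") <- cfg$seed
    out
  })
}

#' Recover decision-tree parameters from a simulated cohort
#'
#' Plug-in estimates: the stratum split from the ratio column, the
#' standard-care admission rate from the latent standard-care flag, and
#' the stratum-specific admission rates from the test-scenario admission
#' flags; plus empirical stay means (pre-onset stay among admitted women,
#' birth stay by preeclampsia status, NICU stay among RDS neonates).
#'
#' @param records A cohort from [simulate_cohort()]. The stratum-specific
#'   rates are only meaningful for a `"test"`-scenario cohort.
#' @return A list with `probs` (a validated
#'   [decision_tree_probabilities()]) and `stay_means` (named numeric;
#'   `NA` where no woman realizes the stay).
#' @export
estimate_parameters <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  low <- records$stratum == "low"
  if (!any(low) || all(low)) {
    stop(paste("degenerate estimate: at least one record is required in",
               "each ratio stratum"), call. = FALSE)
  }
  probs <- decision_tree_probabilities(
    p_hosp_no_test = mean(records$hosp_standard_care),
    share_low = mean(low),
    share_high = mean(!low),
    p_hosp_given_low = mean(records$hospitalized_pre_onset[low]),
    p_hosp_given_high = mean(records$hospitalized_pre_onset[!low])
  )
  mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
  hosp <- records$hospitalized_pre_onset
  stay_means <- c(
    pre_onset_days = mean_or_na(records$pre_onset_days[hosp]),
    birth_pe_days = mean_or_na(records$birth_days[records$pe_within_4wks]),
    birth_no_pe_days = mean_or_na(records$birth_days[!records$pe_within_4wks]),
    nicu_days = mean_or_na(records$nicu_days[records$neonate_rds])
  )
  list(probs = probs, stay_means = stay_means)
}

#' Per-woman realized cost
#'
#' The cost of one simulated trajectory: outpatient care for every woman,
#' the test (doubled under retest) in the test scenario, realized
#' maternal inpatient days (pre-onset plus birth) at the daily rate, a
#' corticosteroid course per pre-onset admission, and realized NICU days
#' at the NICU daily rate.
#'
#' @param records A cohort from [simulate_cohort()].
#' @param costs A [cost_inputs()] object.
#' @param retest Logical; defaults to the flag carried by `records`.
#' @return Numeric vector of per-woman costs (JPY).
#' @export
patient_cost <- function(records, costs = cost_inputs(),
                         retest = attr(records, "retest")) {
  stopifnot(is.data.frame(records), inherits(costs, "cost_inputs"))
  if (is.null(retest)) retest <- FALSE
  test_component <- if (identical(attr(records, "scenario"), "test")) {
    costs$test_cost * (1 + retest)
  } else 0
  costs$outpatient + test_component +
    (records$pre_onset_days + records$birth_days) * costs$hosp_per_day +
    records$hospitalized_pre_onset * costs$corticosteroid +
    records$nicu_days * costs$nicu_per_day
}

#' Monte Carlo mean per-patient cost
#'
#' Empirical mean and standard error of the per-woman cost over a
#' simulated cohort — the stochastic oracle for the analytic
#' [scenario_cost()] per-patient expectation.
#'
#' @inheritParams patient_cost
#' @return A list: `mean`, `se` (sample SD over sqrt(n); `NA` for n = 1),
#'   `n`, `scenario`.
#' @export
monte_carlo_cost <- function(records, costs = cost_inputs(),
                             retest = attr(records, "retest")) {
  x <- patient_cost(records, costs, retest)
  n <- length(x)
  list(mean = mean(x),
       se = if (n > 1) stats::sd(x) / sqrt(n) else NA_real_,
       n = n,
       scenario = attr(records, "scenario"))
}

#' Monte Carlo estimate of the per-patient saving
#'
#' Simulates independent no-test and test cohorts of `n_women` each and
#' returns the difference of their mean per-woman costs with the pooled
#' standard error.
#'
#' @param cfg A [sim_config()]; the test cohort uses `seed`, the no-test
#'   cohort `seed + 1`.
#' @param params Calibrated [pe_parameters()] bundle.
#' @return A list: `saving` (JPY), `se`, `n`, and the two
#'   [monte_carlo_cost()] summaries.
#' @export
monte_carlo_saving <- function(cfg, params) {
  stopifnot(inherits(cfg, "sim_config"))
  coh_test <- simulate_cohort(cfg, params, "test")
  coh_no <- simulate_cohort(sim_config(cfg$n_women, cfg$seed + 1L), params,
                            "no_test")
  mc_test <- monte_carlo_cost(coh_test, params$costs)
  mc_no <- monte_carlo_cost(coh_no, params$costs)
  list(saving = mc_no$mean - mc_test$mean,
       se = sqrt(mc_no$se^2 + mc_test$se^2),
       n = cfg$n_women,
       no_test = mc_no, test = mc_test)
}

#' Write a simulated cohort to CSV
#'
#' One row per woman; columns as documented in [simulate_cohort()].
#'
#' @param records A cohort from [simulate_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(records, path) {
  stopifnot(is.data.frame(records))
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
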