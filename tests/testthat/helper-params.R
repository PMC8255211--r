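# Shared fixtures: all built in code.

base_params <- function(...) pe_parameters(...)

calibrated_params <- function(...) {
  pars <- pe_parameters(...)
  set_nicu_days(pars, calibrate_nicu_days(pars))
}

# A randomized but valid parameter set for property-style tests.
random_params <- function() {
  share_low <- runif(1, 0.3, 0.95)
  probs <- decision_tree_probabilities(
    p_hosp_no_test = runif(1, 0.05, 0.5),
    share_low = share_low,
    share_high = 1 - share_low,
    p_hosp_given_low = runif(1, 0, 0.1),
    p_hosp_given_high = runif(1, 0.2, 0.8)
  )
  costs <- cost_inputs(
    outpatient = runif(1, 0, 1e5),
    hosp_per_day = runif(1, 1e4, 2e5),
    test_cost = runif(1, 1e3, 2e4),
    corticosteroid = runif(1, 0, 1e4),
    nicu_per_day = runif(1, 1e4, 3e5)
  )
  b_no <- runif(1, 5, 12)
  stays <- stay_durations(
    pre_onset_days = runif(1, 1, 10),
    birth_pe_days = b_no + runif(1, 0, 8),
    birth_no_pe_days = b_no,
    nicu_days = runif(1, 1, 30)
  )
  neonatal <- neonatal_assumptions(rds_rate = runif(1, 0.02, 0.3),
                                   rds_reduction = runif(1, 0.05, 0.6))
  pe_parameters(probs = probs, costs = costs, stays = stays,
                neonatal = neonatal,
                cohort = model_cohort(n_model = round(runif(1, 1e3, 1e5))))
}
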