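test_that("overall test-scenario rate is the stratum mixture", {
  # no admissions in either stratum -> zero overall
  p0 <- decision_tree_probabilities(p_hosp_given_low = 0,
                                    p_hosp_given_high = 0)
  expect_identical(overall_test_hosp_rate(p0), 0)
  # equal stratum rates collapse to that rate regardless of the split
  for (x in c(0.1, 0.37, 0.9)) {
    p <- decision_tree_probabilities(share_low = 0.5, share_high = 0.5,
                                     p_hosp_given_low = x,
                                     p_hosp_given_high = x)
    expect_equal(overall_test_hosp_rate(p), x)
  }
})

test_that("expected pre-onset admissions follow the scenario rates", {
  probs <- decision_tree_probabilities()
  cohort <- model_cohort()
  expect_equal(expected_pre_onset_admissions("no_test", probs, cohort),
               31000 * 26 / 180)
  expect_equal(expected_pre_onset_admissions("test", probs, cohort),
               31000 * overall_test_hosp_rate(probs))
  # reported counts bracketed (published 4476 / 2691; rounding convention
  # of the source is ambiguous)
  expect_true(abs(expected_pre_onset_admissions("no_test", probs, cohort) -
                    4477) < 2)
  expect_true(abs(expected_pre_onset_admissions("test", probs, cohort) -
                    2689.5) < 3)
  # degenerate cohort
  z <- model_cohort(n_model = 0)
  expect_identical(expected_pre_onset_admissions("no_test", probs, z), 0)
  expect_error(expected_pre_onset_admissions("later", probs, cohort),
               "unknown scenario")
})

test_that("test-scenario NICU admissions are the thinned no-test count", {
  probs <- decision_tree_probabilities()
  cohort <- model_cohort()
  for (red in c(0, 0.2, 0.7)) {
    neo <- neonatal_assumptions(rds_reduction = red)
    expect_equal(nicu_admissions("test", probs, cohort, neo),
                 (1 - red) * nicu_admissions("no_test", probs, cohort, neo))
  }
})

test_that("scenario_cost components behave by definition", {
  pars <- calibrated_params()
  # retest exactly doubles the testing component and changes nothing else
  single <- scenario_cost("test", pars)
  pars_re <- pars; pars_re$retest <- TRUE
  double <- scenario_cost("test", pars_re)
  expect_equal(double$components[["testing"]],
               2 * single$components[["testing"]])
  keep <- setdiff(names(single$components), "testing")
  expect_equal(double$components[keep], single$components[keep])
  # no testing cost under standard care
  expect_identical(scenario_cost("no_test", pars)$components[["testing"]], 0)
  # all unit costs zero -> total zero
  zero <- pe_parameters(costs = cost_inputs(0, 0, 0, 0, 0),
                        stays = stay_durations(nicu_days = 14))
  expect_identical(scenario_cost("no_test", zero)$total, 0)
  expect_identical(scenario_cost("test", zero)$total, 0)
  # totals are the component sums; per-patient is total over n
  for (sc in c("no_test", "test")) {
    b <- scenario_cost(sc, pars)
    expect_equal(b$total, sum(b$components), tolerance = 1e-12)
    expect_equal(b$per_patient, b$total / 31000)
  }
})

test_that("an uncalibrated NICU stay is an explicit error", {
  expect_error(scenario_cost("test", pe_parameters()), "uncalibrated")
  expect_error(per_patient_saving(pe_parameters()), "uncalibrated")
})

test_that("outpatient and birth components cancel in the saving", {
  pars <- calibrated_params()
  sv <- per_patient_saving(pars)
  expect_identical(sv$component_deltas[["outpatient"]], 0)
  expect_identical(sv$component_deltas[["birth_hospitalization"]], 0)
  # deltas sum to the cohort-level saving
  expect_equal(sum(sv$component_deltas), sv$per_patient_saving * 31000,
               tolerance = 1e-6)
  # budget impact is the unrounded saving scaled to the cohort
  expect_equal(budget_impact(sv), sv$per_patient_saving * 31000,
               tolerance = 0.5)
  expect_equal(budget_impact(sv, model_cohort(n_model = 1)),
               sv$per_patient_saving)
})

test_that("saving is invariant to the outpatient unit cost", {
  ref <- per_patient_saving(calibrated_params())$per_patient_saving
  for (op in c(0, 123.45, 1e6)) {
    pars <- calibrated_params(costs = cost_inputs(outpatient = op))
    expect_equal(per_patient_saving(pars)$per_patient_saving, ref,
                 tolerance = 1e-6 / ref)
  }
})

test_that("saving is affine in test cost with slope -1 (-2 with retest)", {
  pars <- calibrated_params()
  s <- function(tc, retest = FALSE) {
    p <- pars
    p$costs$test_cost <- tc
    p$retest <- retest
    per_patient_saving(p)$per_patient_saving
  }
  expect_equal(s(9000 + 500) - s(9000), -500)
  expect_equal(s(9000 - 1800) - s(9000), 1800)
  expect_equal(s(9000 + 500, TRUE) - s(9000, TRUE), -1000)
})

test_that("saving is affine in nicu_days and decreasing in stratum rates", {
  pars <- calibrated_params()
  s_nicu <- function(d) per_patient_saving(
    set_nicu_days(pars, d))$per_patient_saving
  # equal second differences vanish for an affine map
  d1 <- s_nicu(10) - s_nicu(5)
  d2 <- s_nicu(15) - s_nicu(10)
  expect_equal(d1, d2, tolerance = 1e-9)
  s_rate <- function(field, value) {
    p <- pars
    ov <- stats::setNames(list(value), paste0("probs.", field))
    per_patient_saving(
      apply_scenario(p, scenario_spec("x", ov)))$per_patient_saving
  }
  expect_lt(s_rate("p_hosp_given_low", 0.02),
            s_rate("p_hosp_given_low", 0.0056))
  expect_lt(s_rate("p_hosp_given_high", 0.5),
            s_rate("p_hosp_given_high", 0.4))
})

test_that("calibration matches a brute-force scan and round-trips", {
  pars <- pe_parameters()
  target <- default_calibration_target()
  d <- calibrate_nicu_days(pars, target)
  # independent oracle: scan nicu_days over 0..40 in 0.01-day steps
  grid <- seq(0, 40, by = 0.01)
  savings <- vapply(grid, function(g) per_patient_saving(
    set_nicu_days(pars, g))$per_patient_saving, numeric(1))
  expect_equal(d, grid[which.min(abs(savings - target))], tolerance = 0.005)
  # round trip
  achieved <- per_patient_saving(set_nicu_days(pars, d))$per_patient_saving
  expect_lt(abs(achieved - target), 0.5)
})

test_that("calibration degenerate and failure cases", {
  pars <- pe_parameters()
  floor_saving <- per_patient_saving(set_nicu_days(pars, 0))$per_patient_saving
  expect_equal(calibrate_nicu_days(pars, floor_saving), 0)
  expect_error(calibrate_nicu_days(pars, floor_saving - 1000),
               "inconsistent")
  # affine structure: doubling the NICU day price halves the calibrated stay
  pars2 <- pe_parameters(costs = cost_inputs(nicu_per_day = 2 * 101302))
  expect_equal(calibrate_nicu_days(pars2, default_calibration_target()),
               calibrate_nicu_days(pars, default_calibration_target()) / 2,
               tolerance = 1e-9)
})

test_that("length-of-stay diagnostic reports, never fails", {
  # all component stays equal -> episode-weighted average equals that stay
  st <- stay_durations(pre_onset_days = 7, birth_pe_days = 7,
                       birth_no_pe_days = 7, nicu_days = 1)
  rep7 <- check_los_consistency(stays = st)
  expect_equal(rep7$implied_avg_los, c(7, 7))
  # zero birth episodes -> average is the pre-onset stay
  rep0 <- check_los_consistency(birth_rate = 0)
  expect_equal(rep0$implied_avg_los, c(4, 4))
  # defaults: deviations from the reported 10.4 / 10.2 are reported as data
  repd <- check_los_consistency()
  expect_equal(repd$deviation, repd$implied_avg_los - c(10.4, 10.2))
  expect_s3_class(repd, "data.frame")
})

test_that("cost results serialize to long CSV and JSON", {
  pars <- calibrated_params()
  sv <- per_patient_saving(pars)
  df <- breakdown_df(sv$no_test, sv$test)
  expect_equal(nrow(df), 14)  # 6 components + total, two scenarios
  expect_named(df, c("scenario", "component", "cohort_cost_jpy"))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_breakdown_csv(df, csv)
  expect_equal(utils::read.csv(csv)$cohort_cost_jpy, df$cohort_cost_jpy)
  js <- withr::local_tempfile(fileext = ".json")
  write_saving_json(sv, js)
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$per_patient_saving_jpy, sv$per_patient_saving)
  expect_equal(parsed$component_deltas_jpy$outpatient, 0)
})
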