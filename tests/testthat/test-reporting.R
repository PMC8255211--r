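test_that("cmd_base_case writes deterministic files that match the model", {
  out <- withr::local_tempdir()
  res <- suppressMessages(cmd_base_case(default_config_path(), out))
  expect_true(file.exists(file.path(out, "base_case_breakdown.csv")))
  expect_true(file.exists(file.path(out, "base_case_saving.json")))
  expect_true(file.exists(file.path(out, "manifest.json")))
  # files agree with a direct model call
  direct <- per_patient_saving(calibrated_params())
  parsed <- jsonlite::read_json(file.path(out, "base_case_saving.json"),
                                simplifyVector = TRUE)
  expect_equal(parsed$per_patient_saving_jpy, direct$per_patient_saving)
  expect_equal(res$saving$per_patient_saving, direct$per_patient_saving)
  # rerun is byte-identical for the data outputs
  out2 <- withr::local_tempdir()
  suppressMessages(cmd_base_case(default_config_path(), out2))
  expect_identical(readLines(file.path(out, "base_case_breakdown.csv")),
                   readLines(file.path(out2, "base_case_breakdown.csv")))
  expect_identical(readLines(file.path(out, "base_case_saving.json")),
                   readLines(file.path(out2, "base_case_saving.json")))
})

test_that("an explicit nicu_days in the config suppresses calibration", {
  out <- withr::local_tempdir()
  cfg <- file.path(out, "cfg.json")
  pars <- set_nicu_days(pe_parameters(), 10)
  write_config(pars, cfg)
  expect_no_message(res <- cmd_base_case(cfg, out), message = "calibrated")
  expect_equal(res$params$stays$nicu_days, 10)
  expect_true(is.na(attr(res$params, "calibrated_nicu_days")))
})

test_that("zero-cost configuration saves only the (negative) test cost", {
  out <- withr::local_tempdir()
  cfg <- file.path(out, "cfg.json")
  pars <- pe_parameters(costs = cost_inputs(0, 0, 9000, 0, 0))
  write_config(set_nicu_days(pars, 0), cfg)
  res <- suppressMessages(cmd_base_case(cfg, out))
  expect_equal(res$saving$per_patient_saving, -9000)
})

test_that("cmd_sensitivity tabulates the built-ins and matches direct calls", {
  out <- withr::local_tempdir()
  tab <- suppressMessages(cmd_sensitivity(default_config_path(),
                                          out_dir = out))
  expect_equal(nrow(tab), 8)
  csv <- utils::read.csv(file.path(out, "sensitivity.csv"))
  expect_equal(nrow(csv), 8)
  direct <- run_sensitivity(builtin_scenarios(), calibrated_params())
  expect_equal(csv$saving_jpy, round(direct$saving_jpy))
  # empty scenario file -> base-only table
  empty <- file.path(out, "none.json")
  writeLines("[]", empty)
  tab0 <- suppressMessages(cmd_sensitivity(default_config_path(),
                                           scenarios_path = empty,
                                           out_dir = out))
  expect_equal(tab0$scenario, "base_case")
})

test_that("cmd_simulate reports analytic-vs-Monte-Carlo agreement", {
  out <- withr::local_tempdir()
  rep <- suppressMessages(cmd_simulate(default_config_path(), n = 20000,
                                       seed = 17, out_dir = out))
  expect_true(file.exists(file.path(out, "cohort_no_test.csv")))
  expect_true(file.exists(file.path(out, "cohort_test.csv")))
  expect_equal(rep$per_patient_cost$no_test$flag, "PASS")
  expect_equal(rep$per_patient_cost$test$flag, "PASS")
  # reproducible numbers for a fixed seed
  rep2 <- suppressMessages(cmd_simulate(default_config_path(), n = 20000,
                                        seed = 17,
                                        out_dir = withr::local_tempdir()))
  expect_identical(rep$per_patient_saving$monte_carlo,
                   rep2$per_patient_saving$monte_carlo)
  # n = 1: report generated with the SE flagged undefined
  rep1 <- suppressMessages(cmd_simulate(default_config_path(), n = 1,
                                        seed = 17,
                                        out_dir = withr::local_tempdir()))
  expect_equal(rep1$per_patient_cost$test$flag, "SE_UNDEFINED")
})

test_that("cmd_calibrate writes the calibrated stay and manifests carry provenance", {
  out <- withr::local_tempdir()
  days <- suppressMessages(cmd_calibrate(default_config_path(), out))
  parsed <- jsonlite::read_json(file.path(out, "calibration.json"),
                                simplifyVector = TRUE)
  expect_equal(parsed$nicu_days, days)
  expect_lt(abs(parsed$achieved_saving_jpy - parsed$target_saving_jpy), 0.5)
  man <- jsonlite::read_json(file.path(out, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$command, "calibrate")
  expect_equal(man$config_digest,
               unname(tools::md5sum(default_config_path())))
  expect_equal(man$package_version,
               as.character(utils::packageVersion("pecost")))
})

test_that("the shipped command-line wrapper runs end to end", {
  script <- system.file("cli", "pecost.R", package = "pecost")
  expect_true(nzchar(script))
  out <- withr::local_tempdir()
  rscript <- file.path(R.home("bin"), "Rscript")
  libs <- paste0("R_LIBS=", paste(.libPaths(),
                                  collapse = .Platform$path.sep))
  status <- system2(rscript, c(script, "base-case", "--out-dir", out),
                    env = libs, stdout = FALSE, stderr = FALSE)
  expect_equal(status, 0L)
  expect_true(file.exists(file.path(out, "base_case_saving.json")))
})
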