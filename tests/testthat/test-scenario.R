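test_that("treatment modes honor their contracts", {
  cfg_chemo <- fast_combo_config()
  cfg_chemo$schedule$mode <- "chemo"
  r_chemo <- run_scenario(cfg_chemo)
  expect_null(r_chemo$temperature)
  expect_equal(r_chemo$efficacy$fkc_heat, 0)
  expect_gt(r_chemo$efficacy$fkc_drug, 0)
  expect_equal(r_chemo$efficacy$fkc_combined, r_chemo$efficacy$fkc_drug,
               tolerance = 1e-12)

  cfg_mht <- fast_combo_config()
  cfg_mht$schedule$mode <- "mht_only"
  r_mht <- run_scenario(cfg_mht)
  expect_null(r_mht$drug)
  expect_equal(r_mht$efficacy$fkc_drug, 0)
  expect_gt(r_mht$efficacy$fkc_heat, 0)
  expect_equal(r_mht$efficacy$fkc_combined, r_mht$efficacy$fkc_heat,
               tolerance = 1e-12)
})

test_that("combination therapy beats both single modalities", {
  cfg <- fast_combo_config()
  r_combo <- run_scenario(cfg)
  cfg_chemo <- cfg; cfg_chemo$schedule$mode <- "chemo"
  cfg_mht <- cfg; cfg_mht$schedule$mode <- "mht_only"
  r_chemo <- run_scenario(cfg_chemo)
  r_mht <- run_scenario(cfg_mht)
  expect_gt(r_combo$efficacy$fkc_combined, r_mht$efficacy$fkc_combined)
  expect_gt(r_combo$efficacy$fkc_combined, r_chemo$efficacy$fkc_combined)
  # all conservation audits hold on a live pipeline run
  expect_lt(r_combo$audits$thermal_energy, 1e-3)
  expect_lt(r_combo$audits$drug_mass, 5e-3)
  expect_lt(r_combo$audits$flow_mass, 1e-3)
})

test_that("fixed-step runs are bit-reproducible and sweeps are consistent", {
  cfg <- fast_combo_config()
  r1 <- run_scenario(cfg)
  r2 <- run_scenario(cfg)
  expect_identical(r1$drug$series, r2$drug$series)
  expect_identical(r1$efficacy, r2$efficacy)
  expect_identical(r1$temperature$T, r2$temperature$T)
  # a singleton sweep reproduces the direct run exactly (cache correctness)
  sw <- run_sweep(cfg, axis = "delay", values = cfg$schedule$delay)
  expect_equal(sw$summary$fkc_combined, r1$efficacy$fkc_combined,
               tolerance = 1e-12)
  expect_equal(sw$summary$peak_mean_ci, r1$drug$peaks["CI", "value"],
               tolerance = 1e-12)
})

test_that("sweep axes modify the intended stage and record failures", {
  cfg <- fast_combo_config()
  sw <- run_sweep(cfg, axis = "dose", values = c(0.5, 1))
  expect_true(all(diff(sw$summary$fkc_combined) > 0))
  # failing values are recorded without aborting the sweep
  sw2 <- run_sweep(cfg, axis = "pore_size", values = c(-1, 200e-9))
  expect_false(is.na(sw2$summary$error[1]))
  expect_true(is.na(sw2$summary$error[2]))
  expect_gt(sw2$summary$fkc_combined[2], 0)
})

test_that("presets load and resolve", {
  expect_setequal(scenario_preset(),
                  c("chemo_baseline", "mht_11kAm", "mht_13kAm", "combo_9h"))
  cfg <- scenario_preset("combo_9h")
  expect_s3_class(cfg, "scenario_config")
  expect_equal(cfg$schedule$delay, 9 * 3600)
  expect_equal(cfg$field$amplitude, 13e3)
  expect_error(scenario_preset("nope"), "unknown preset")
})

test_that("scenario outputs serialize to the documented layout", {
  cfg <- fast_combo_config()
  r <- run_scenario(cfg)
  dir <- withr::local_tempdir()
  write_scenario_outputs(r, dir)
  expect_true(file.exists(file.path(dir, "summary.json")))
  expect_true(file.exists(file.path(dir, "timeseries.csv")))
  expect_true(file.exists(file.path(dir, "resolved_config.yaml")))
  expect_true(file.exists(file.path(dir, "profiles", "radial_profiles.csv")))
  js <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(js$fkc_combined, r$efficacy$fkc_combined, tolerance = 1e-9)
  cfg2 <- load_scenario(file.path(dir, "resolved_config.yaml"))
  expect_equal(cfg2, cfg)
})

test_that("mnp power table exposes the calibration chain", {
  tab <- mnp_power_table(scenario_preset("mht_11kAm"))
  expect_equal(tab$tau_eff_s,
               tab$tau_B_s * tab$tau_N_s / (tab$tau_B_s + tab$tau_N_s),
               tolerance = 1e-12)
  expect_gt(tab$qmnp_w_m3, 1e5)
})
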