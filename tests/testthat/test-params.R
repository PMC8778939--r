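test_that("tabulated transport and kinetic defaults carry the canonical values", {
  d <- drug_params()
  expect_equal(d$free_drug_diffusivity, 3.4e-10)           # 3.4e-6 cm2/s
  expect_equal(d$vessel_permeability_free, 3e-6)           # 3e-4 cm/s
  expect_equal(d$binding_on, 1.5)                          # 1.5e3 1/(M s)
  expect_equal(d$binding_off, 8e-3)
  expect_equal(d$internalization, 5e-5)
  expect_equal(d$accessible_fraction, 0.3)
  expect_equal(d$receptor_concentration, 0.01)             # 1e-5 M
  expect_equal(d$survival_constant, 0.6603)
  expect_equal(d$release_rate_at_42, 0.05409)

  f <- flow_params()
  expect_equal(f$vessel_hydraulic_conductivity, 2.8e-9 / 133.322,
               tolerance = 1e-12)
  expect_equal(f$hydraulic_conductivity, 4.13e-12 / 133.322,
               tolerance = 1e-12)
  expect_equal(f$vessel_area_density, 2e4)                 # 200 1/cm
  expect_equal(convert_units(f$vascular_pressure, "Pa", "mmHg"), 15.6)
  expect_equal(convert_units(f$plasma_osmotic_pressure, "Pa", "mmHg"), 20)
  expect_equal(convert_units(f$interstitial_osmotic_pressure, "Pa", "mmHg"), 15)
  expect_equal(f$osmotic_reflection, 0.82)

  th <- thermodox:::.default_thermal()
  expect_equal(th$normal$density, 1060)
  expect_equal(th$tumor$density, 1040)
  expect_equal(th$injection$density, 5180)
  expect_equal(th$normal$thermal_conductivity, 0.59)
  expect_equal(th$tumor$thermal_conductivity, 0.57)
  expect_equal(th$injection$thermal_conductivity, 528)
  expect_equal(th$tumor$specific_heat, 3600)
  expect_equal(th$injection$specific_heat, 670)

  a <- arrhenius_params()
  expect_equal(a$frequency_factor, 1.98e106)
  expect_equal(a$activation_energy, 6.67e5)
  expect_equal(a$gas_constant, 8.314)
})

test_that("field safety product is enforced and relaxable", {
  # 13e3 * 400e3 = 5.2e9 exceeds the 5e9 default tolerance limit
  expect_error(field_spec(amplitude = 13e3, frequency = 400e3),
               "safety product")
  expect_silent(field_spec(amplitude = 13e3, frequency = 400e3,
                           safety_product_limit = 5.3e9))
  expect_silent(field_spec(amplitude = 11e3, frequency = 400e3))
})

test_that("dose outside the documented range requires an explicit override", {
  expect_error(drug_params(initial_plasma_dose = 2.5), "0.5, 1.5")
  expect_silent(drug_params(initial_plasma_dose = 2.5,
                            allow_out_of_range = TRUE))
  expect_silent(drug_params(initial_plasma_dose = 1.5))
})

test_that("parameter invariants are validated", {
  expect_error(magnetic_spec(core_diameter = 25e-9), "20 nm")
  expect_error(magnetic_spec(volume_fraction = 1.2), "(0, 1)")
  expect_error(field_spec(on_time = 100, off_time = 50), "off_time")
  expect_error(flow_params(osmotic_reflection = 1.3), "\\[0, 1\\]")
  expect_error(drug_params(release_threshold_low = 43), "threshold")
  expect_error(scenario_config(geometry = list(injection_radius = 0.02)),
               "injection_radius < tumor_radius")
})

test_that("an empty scenario document resolves to the full default configuration", {
  cfg <- load_scenario("")
  ref <- scenario_config()
  expect_equal(cfg, ref)
})

test_that("unknown scenario keys are rejected with their key path", {
  expect_error(load_scenario("drug:\n  not_a_key: 1\n"), "drug.not_a_key")
  expect_error(load_scenario("nonsense:\n  a: 1\n"), "unknown block")
})

test_that("convenience unit keys are converted at the boundary", {
  cfg <- load_scenario("geometry:\n  tumor_radius_cm: 1.2\nschedule:\n  delay_h: 9\n")
  expect_equal(cfg$geometry$tumor_radius, 0.012)
  expect_equal(cfg$schedule$delay, 9 * 3600)
})

test_that("serializing and reloading a configuration is idempotent", {
  cfg <- scenario_config(
    field = field_spec(amplitude = 12e3),
    drug = drug_params(initial_plasma_dose = 0.75),
    schedule = list(delay = 4 * 3600))
  txt <- scenario_to_yaml(cfg)
  cfg2 <- load_scenario(txt)
  expect_equal(cfg2, cfg)
  expect_equal(scenario_to_yaml(cfg2), txt)
})
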