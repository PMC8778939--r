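test_that("release rate is zero at normothermia and plateaus above 42 C", {
  d <- drug_params()
  expect_equal(release_rate(37, d), 0)
  expect_equal(release_rate(38.9, d), 0)
  expect_equal(release_rate(42, d), 0.05409)
  expect_equal(release_rate(45, d), 0.05409)
  # monotone ramp in between
  temps <- seq(39, 42, by = 0.1)
  expect_true(all(diff(release_rate(temps, d)) >= 0))
  expect_equal(release_rate(40.5, d), 0.05409 / 2)   # linear ramp midpoint
  d2 <- drug_params(release_ramp = "exponential")
  expect_true(all(diff(release_rate(temps, d2)) >= 0))
  expect_equal(release_rate(42, d2), 0.05409)
})

test_that("transvascular source reproduces the Patlak formula and limits", {
  sv <- 2e4; P <- 3e-6
  # diffusion-only limit: Pe = 0
  expect_equal(transmural_source(1, 0.2, phiB = 0, P, sigma_f = 0, sv),
               P * sv * 0.8, tolerance = 1e-12)
  expect_equal(transmural_source(1, 0.2, phiB = 1e-3, P, sigma_f = 1, sv),
               P * sv * 0.8, tolerance = 1e-12)
  # equilibrium with full reflection: no driving force
  expect_equal(transmural_source(0.5, 0.5, phiB = 1e-3, P, sigma_f = 1, sv), 0)
  # direct arithmetic oracle with the tabulated values
  phiB <- 6e-4; sf <- 0.15; cpl <- 1; cc <- 0
  pe <- phiB * (1 - sf) / (P * sv)
  expected <- phiB * (1 - sf) * cpl + P * sv * (cpl - cc) * pe / (exp(pe) - 1)
  expect_equal(transmural_source(cpl, cc, phiB, P, sf, sv), expected,
               tolerance = 1e-12)
  # Patlak factor -> 1 as Pe -> 0 (continuity of the convective correction)
  pes <- 10^seq(-1, -9, by = -1)
  pat <- thermodox:::.patlak(pes)
  expect_true(all(abs(pat - 1) < pes))
  expect_equal(thermodox:::.patlak(0), 1)
  # pure convective branch
  expect_equal(transmural_source(1, 0, phiB, P = 0, sf, sv),
               phiB * (1 - sf), tolerance = 1e-12)
})

test_that("plasma forcing decays mono-exponentially from the bolus", {
  d <- drug_params()
  expect_equal(plasma_concentration(0, d), d$initial_plasma_dose)
  expect_equal(plasma_concentration(d$plasma_decay, d),
               d$initial_plasma_dose * exp(-1), tolerance = 1e-12)
  expect_lt(plasma_concentration(3600, d, "free_drug"),
            plasma_concentration(3600, d, "tsl"))
})

test_that("well-mixed reduction matches an independent stiff ODE oracle", {
  skip_if_not_installed("deSolve")
  g <- default_grid(n = c(10, 50, 20))
  # switch off all spatial coupling: no flow, negligible diffusion
  flow <- flow_params(vessel_hydraulic_conductivity = 0)
  fsol <- solve_ifp(g, flow)
  d <- drug_params(tsl_diffusivity = 1e-30, free_drug_diffusivity = 1e-30,
                   vessel_permeability_tsl = 2e-8,
                   filtration_reflection_tsl = 0.2)
  kel_const <- 2e-3
  horizon <- 12 * 3600
  kel <- list(times = c(-1, horizon + 1),
              mat = matrix(kel_const, 2, g$n))
  hist <- run_transport(g, fsol, d, flow, mode = "tsl", kel_schedule = kel,
                        horizon = horizon, dt = 3.6, reaction_substeps = 4,
                        record_every = 500)
  # independent ODE integration of the same four-compartment kinetics
  kappa <- 2e-8 * 2e4        # P S/V, Pe = 0 here
  kon <- d$binding_on * d$receptor_concentration / d$accessible_fraction
  koff <- d$binding_off / d$accessible_fraction
  rhs <- function(t, y, parms) {
    cp <- d$initial_plasma_dose * exp(-t / d$plasma_decay)
    list(c(-kel_const * y[1] + kappa * (cp - y[1]),
           kel_const * y[1] - kon * y[2] + koff * y[3],
           kon * y[2] - koff * y[3] - d$internalization * y[3],
           d$internalization * y[3]))
  }
  ode <- deSolve::lsoda(c(0, 0, 0, 0), times = c(0, horizon / 2, horizon),
                        func = rhs, parms = NULL, rtol = 1e-11, atol = 1e-14)
  i_node <- which(g$region == "tumor")[10]
  expect_equal(hist$CL[i_node], unname(ode[3, 2]), tolerance = 1e-6)
  expect_equal(hist$CF[i_node], unname(ode[3, 3]), tolerance = 1e-6)
  expect_equal(hist$CB[i_node], unname(ode[3, 4]), tolerance = 1e-6)
  expect_equal(hist$CI[i_node], unname(ode[3, 5]), tolerance = 1e-6)
  # receptor-limited bound pool: cannot exceed the binding equilibrium ratio
  expect_lt(max(hist$CB / pmax(hist$CF, 1e-30)),
            kon / koff * (1 + 1e-6))
})

test_that("with sinks disabled and sealed vessels, drug mass is conserved", {
  g <- default_grid(n = c(10, 50, 20))
  flow <- flow_params(vessel_hydraulic_conductivity = 0)
  fsol <- solve_ifp(g, flow)
  # slow free-drug diffusion so the bolus cannot reach the open outer
  # boundary within the horizon (an effectively sealed domain)
  d <- drug_params(vessel_permeability_tsl = 0, filtration_reflection_tsl = 1,
                   vessel_permeability_free = 0, internalization = 0,
                   free_drug_diffusivity = 3.4e-11)
  # an initial interior bolus of carrier and free drug, far from the boundary
  init <- list(CL = exp(-(g$r / 4e-3)^2), CF = 0.5 * exp(-(g$r / 4e-3)^2))
  hist <- run_transport(g, fsol, d, flow, mode = "tsl", kel_schedule = NULL,
                        horizon = 72 * 3600, dt = 36, record_every = 100,
                        init = init)
  m0 <- sum((init$CL + init$CF) * g$volume)
  m1 <- sum((hist$CL + hist$CF + hist$CB + hist$CI) * g$volume)
  expect_equal(m1 / m0, 1, tolerance = 1e-3)
})

test_that("zero dose leaves every compartment identically zero", {
  g <- default_grid(n = c(10, 50, 20))
  fsol <- solve_ifp(g, flow_params())
  d <- drug_params(initial_plasma_dose = 0, allow_out_of_range = TRUE)
  hist <- run_transport(g, fsol, d, flow_params(), mode = "tsl",
                        horizon = 6 * 3600, dt = 36, record_every = 100)
  expect_equal(max(abs(c(hist$CL, hist$CF, hist$CB, hist$CI))), 0)
})

test_that("internalized drug is monotone and mass audit closes on a live run", {
  g <- default_grid(n = c(10, 50, 20))
  fsol <- solve_ifp(g, flow_params())
  kel <- list(times = c(2 * 3600, 3 * 3600),
              mat = matrix(rep(c(0.05, 0.05), g$n), 2, g$n))
  hist <- run_transport(g, fsol, drug_params(), flow_params(), mode = "tsl",
                        kel_schedule = kel, horizon = 24 * 3600, dt = 14.4,
                        record_every = 100)
  expect_true(all(diff(hist$series$CI_mean) >= -1e-12))
  expect_lt(hist$mass_audit, 5e-3)
  # in tsl mode with the field never switched on, free drug stays ~ 0
  quiet <- run_transport(g, fsol, drug_params(), flow_params(), mode = "tsl",
                         kel_schedule = NULL, horizon = 24 * 3600, dt = 14.4,
                         record_every = 100)
  expect_lt(max(quiet$series$CF_mean), 1e-12)
  expect_gt(max(quiet$series$CL_mean), 0.01)
})

test_that("chemo mode carries no liposome compartment", {
  g <- default_grid(n = c(10, 50, 20))
  fsol <- solve_ifp(g, flow_params())
  hist <- run_transport(g, fsol, drug_params(), flow_params(), mode = "chemo",
                        horizon = 12 * 3600, dt = 14.4, record_every = 100)
  expect_equal(max(hist$series$CL_mean), 0)
  expect_gt(max(hist$series$CB_mean), 0)
  expect_gt(max(hist$series$CI_mean), 0)
})
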