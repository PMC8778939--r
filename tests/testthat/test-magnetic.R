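# Frozen expected values computed directly from the closed forms with
# kB = 1.380649e-23 J/K (independent arithmetic, not the package path).

test_that("relaxation times match direct evaluation of the closed forms", {
  spec <- magnetic_spec(anisotropy_constant = 2.3e4)  # spec of the worked case
  Ts <- 310.15
  kT <- 1.380649e-23 * Ts
  vh <- pi / 6 * (10e-9)^3
  rt <- relaxation_times(spec, Ts)
  expect_equal(rt$brown, 3 * 1e-3 * vh / kT, tolerance = 1e-12)
  expect_equal(rt$brown, 3.668e-7, tolerance = 1e-3)
  gamma <- 2.3e4 * vh / kT
  expect_equal(rt$anisotropy_ratio, gamma, tolerance = 1e-12)
  expect_equal(rt$anisotropy_ratio, 2.813, tolerance = 1e-3)
  tauN <- sqrt(pi) / 2 * 1e-9 * exp(gamma) / sqrt(gamma)
  expect_equal(rt$neel, tauN, tolerance = 1e-12)
  expect_equal(rt$neel, 8.80e-9, tolerance = 2e-3)
  expect_equal(rt$effective, rt$brown * rt$neel / (rt$brown + rt$neel),
               tolerance = 1e-12)
  expect_equal(rt$effective, 8.6e-9, tolerance = 3e-3)
})

test_that("the effective time never exceeds either mechanism", {
  set.seed(42)
  for (i in 1:50) {
    spec <- magnetic_spec(core_diameter = runif(1, 5e-9, 19e-9),
                          coating_thickness = runif(1, 0, 5e-9),
                          anisotropy_constant = runif(1, 5e3, 4e4),
                          suspension_viscosity = 10^runif(1, -3.5, -2))
    rt <- relaxation_times(spec, runif(1, 300, 320))
    expect_lte(rt$effective, min(rt$brown, rt$neel))
    expect_gt(rt$effective, 0)
  }
})

test_that("chord susceptibility follows the Langevin chord and its limits", {
  spec <- magnetic_spec()
  Ts <- 310.15
  kT <- 1.380649e-23 * Ts
  vm <- pi / 6 * (10e-9)^3
  chi_i <- 4 * pi * 1e-7 * 446e3^2 * vm / (3 * kT)
  # small-field limit -> initial susceptibility
  f0 <- field_spec(amplitude = 1e-6)
  expect_equal(equilibrium_susceptibility(spec, f0, Ts), chi_i,
               tolerance = 1e-6)
  # worked case: xi = 0.891 at 13 kA/m, chord factor ~ 0.95
  f13 <- field_spec(amplitude = 13e3, safety_product_limit = 5.3e9)
  xi <- 4 * pi * 1e-7 * 446e3 * 13e3 * vm / kT
  expect_equal(xi, 0.891, tolerance = 1e-3)
  chord <- equilibrium_susceptibility(spec, f13, Ts) / chi_i
  expect_equal(chord, 3 / xi * (1 / tanh(xi) - 1 / xi), tolerance = 1e-12)
  expect_equal(chord, 0.95, tolerance = 5e-3)
  # monotone decrease with amplitude
  amps <- seq(1e3, 15e3, length.out = 20)
  chis <- vapply(amps, function(a) equilibrium_susceptibility(
    spec, field_spec(amplitude = a, safety_product_limit = 1e10), Ts), 0)
  expect_true(all(diff(chis) < 0))
})

test_that("dissipated power obeys its exact scalings and limits", {
  spec <- magnetic_spec()
  expect_equal(volumetric_power(spec, field_spec(amplitude = 1e-12)), 0,
               tolerance = 1e-20)
  # Q / (chi0 Hm^2) is amplitude-invariant (quadratic law at fixed chi0)
  qn <- function(a) {
    f <- field_spec(amplitude = a, safety_product_limit = 1e10)
    volumetric_power(spec, f) / (equilibrium_susceptibility(spec, f) * a^2)
  }
  expect_equal(qn(5e3), qn(15e3), tolerance = 1e-12)
  # linear in volume fraction
  q1 <- volumetric_power(magnetic_spec(volume_fraction = 0.01),
                         field_spec(amplitude = 11e3))
  q3 <- volumetric_power(magnetic_spec(volume_fraction = 0.03),
                         field_spec(amplitude = 11e3))
  expect_equal(q3 / q1, 3, tolerance = 1e-12)
  # frequency bracket maximal at 2 pi f tau_eff = 1
  tau <- relaxation_times(spec)$effective
  freqs <- seq(0.2, 5, by = 0.002) / (2 * pi * tau)
  bracket <- vapply(freqs, function(f) {
    fs <- field_spec(amplitude = 1e3, frequency = f,
                     safety_product_limit = Inf)
    volumetric_power(spec, fs) /
      (spec$volume_fraction * 4 * pi * 1e-7 *
         equilibrium_susceptibility(spec, fs) * 1e6 * f)
  }, 0)
  f_star <- freqs[which.max(bracket)]
  expect_equal(2 * pi * f_star * tau, 1, tolerance = 3e-3)
  # non-negative power across random physical specs
  set.seed(7)
  for (i in 1:25) {
    s <- magnetic_spec(core_diameter = runif(1, 6e-9, 18e-9),
                       anisotropy_constant = runif(1, 5e3, 4e4))
    expect_gte(volumetric_power(s, field_spec(amplitude = 11e3)), 0)
  }
})

test_that("default power density is regression-pinned", {
  q13 <- volumetric_power(magnetic_spec(),
                          field_spec(amplitude = 13e3,
                                     safety_product_limit = 5.3e9))
  expect_equal(q13, 2361581, tolerance = 1e-4)
})
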