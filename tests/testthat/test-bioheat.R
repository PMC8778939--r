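test_that("with no sources the uniform 37 C state is preserved", {
  g <- default_grid(n = c(10, 50, 30))
  th <- uniform_thermal(qm = 0)
  h <- solve_bioheat(g, th, qmnp = 0, duration = 600, cooldown = 0, dt = 7.2)
  expect_lt(max(abs(h$T - 37)), 1e-9)
})

test_that("steady state matches the screened-Poisson closed form", {
  q <- 5e5; perf <- 5e-4
  th <- uniform_thermal(k = 0.57, rho = 1040, C = 3600, perfusion = perf,
                        qm = 0)
  beta <- 1000 * 3600 * perf
  g <- default_grid(n = c(60, 120, 120))
  steady <- solve_bioheat_steady(g, th, q)
  ana <- analytic_screened_sphere(g$r, a = 2.5e-3, R = 3e-2, q = q,
                                  k = 0.57, beta = beta)
  rise_num <- steady - 37; rise_ana <- ana - 37
  expect_lt(max(abs(rise_num - rise_ana)) / max(rise_ana), 5e-3)
})

test_that("steady energy balance closes to bookkeeping precision", {
  g <- default_grid()
  h <- solve_bioheat(g, thermodox:::.default_thermal(), qmnp = 1.5e6,
                     duration = 60, cooldown = 0, dt = 7.2)
  expect_lt(h$energy_audit, 1e-3)
})

test_that("temperature never falls below the arterial floor with sources on", {
  g <- default_grid(n = c(10, 50, 30))
  h <- solve_bioheat(g, thermodox:::.default_thermal(), qmnp = 2e6,
                     duration = 1800, cooldown = 1800, dt = 7.2)
  expect_gte(min(h$T), 37 - 1e-9)
})

test_that("grid refinement converges at second order for the steady field", {
  th <- uniform_thermal(perfusion = 5e-4, qm = 0)
  probe <- function(n) {
    g <- default_grid(n = n)
    solve_bioheat_steady(g, th, 5e5)[1]
  }
  t1 <- probe(c(20, 60, 60))
  t2 <- probe(c(40, 120, 120))
  t4 <- probe(c(80, 240, 240))
  order <- log2(abs(t1 - t2) / abs(t2 - t4))
  expect_gt(order, 1.5)
  expect_lt(order, 2.7)
})

test_that("Arrhenius damage matches the constant-temperature closed form", {
  g <- default_grid(n = c(10, 50, 30))
  const_history <- function(temp_c, hours) {
    times <- seq(0, hours * 3600, by = 60)
    list(times = times, T = matrix(temp_c, length(times), g$n))
  }
  a <- arrhenius_params()
  closed <- function(temp_c, hours)
    a$frequency_factor *
      exp(-a$activation_energy / (a$gas_constant * (temp_c + 273.15))) *
      hours * 3600

  d37 <- arrhenius_survival(const_history(37, 1), a)
  expect_equal(d37$omega[1], closed(37, 1), tolerance = 1e-6)
  expect_equal(closed(37, 1), 3.3e-3, tolerance = 2e-2)
  expect_gt(min(d37$survival), 0.99)

  d43 <- arrhenius_survival(const_history(43, 1), a)
  expect_equal(d43$omega[1], closed(43, 1), tolerance = 1e-6)
  expect_equal(closed(43, 1), 0.44, tolerance = 2e-2)
  expect_equal(1 - d43$survival[1], 0.35, tolerance = 3e-2)

  # doubling exposure exactly doubles the damage integral
  d43b <- arrhenius_survival(const_history(43, 2), a)
  expect_equal(d43b$omega[1], 2 * d43$omega[1], tolerance = 1e-12)
  expect_equal(d43$survival, exp(-d43$omega), tolerance = 1e-12)
})

test_that("the calibrated 11 kA/m exposure plateaus within the hour", {
  g <- default_grid()
  q <- volumetric_power(magnetic_spec(), field_spec(amplitude = 11e3))
  h <- solve_bioheat(g, thermodox:::.default_thermal(), q,
                     duration = 3600, cooldown = 0, dt = 7.2)
  tp <- time_to_plateau(h, fraction = 0.95)
  expect_gt(tp / 60, 5)
  expect_lt(tp / 60, 30)
  # end-of-hour center value is within 1% of steady (plateau reached)
  expect_equal(h$T[nrow(h$T), 1] - 37, h$steady[1] - 37, tolerance = 1e-2)
})
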