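# Shared builders for fast test configurations.

default_geometry <- function() {
  list(injection_radius = 2.5e-3, tumor_radius = 1e-2, outer_radius = 3e-2)
}

default_grid <- function(n = c(20, 60, 60)) radial_grid(default_geometry(), n)

# uniform thermal properties in all three regions (single-material medium)
uniform_thermal <- function(k = 0.57, rho = 1040, C = 3600,
                            perfusion = 5e-4, qm = 0, alpha_injection = 1) {
  mk <- function(alpha) tissue_thermal_params(
    density = rho, specific_heat = C, thermal_conductivity = k,
    perfusion_rate = perfusion, metabolic_heat = qm, mnp_source_scale = alpha)
  list(normal = mk(0), tumor = mk(0), injection = mk(alpha_injection))
}

# a light scenario configuration for pipeline tests: short horizon, coarse
# time step, 2 h delay
fast_combo_config <- function(...) {
  scenario_config(
    field = field_spec(amplitude = 13e3, safety_product_limit = 5.3e9),
    schedule = list(mode = "combination", delay = 2 * 3600,
                    horizon = 24 * 3600),
    solver = list(n_injection = 10, n_tumor = 50, n_normal = 30,
                  dt_thermal = 7.2, dt_transport = 14.4, cooldown = 3600),
    ...)
}

# Analytic steady temperature for a uniform source sphere (radius a) in a
# uniform perfused medium of radius R with T(R) = Tb: the screened-Poisson
# (modified Helmholtz) closed form. Independent of the finite-volume path.
analytic_screened_sphere <- function(r, a, R, q, k, beta, Tb = 37) {
  m <- sqrt(beta / k)
  # theta = T - Tb; inside: q/beta + A sinh(m r)/r; outside: C sinh(m (R-r))/r
  # matching value and flux at r = a
  sa <- sinh(m * a); ca <- cosh(m * a)
  sRa <- sinh(m * (R - a)); cRa <- cosh(m * (R - a))
  # unknowns x = (A, C):  value: q/beta + A sa/a = C sRa/a
  # flux: A (m ca / a - sa / a^2) = C (-m cRa / a - sRa / a^2)
  M <- rbind(c(sa / a, -sRa / a),
             c(m * ca / a - sa / a^2, m * cRa / a + sRa / a^2))
  rhs <- c(-q / beta, 0)
  x <- solve(M, rhs)
  theta <- ifelse(r <= a,
                  q / beta + x[1] * ifelse(r == 0, m, sinh(m * r) / r),
                  x[2] * sinh(m * (R - r)) / r)
  Tb + theta
}
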