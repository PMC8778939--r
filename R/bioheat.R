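# Transient Pennes bioheat solver and Arrhenius thermal damage.

# Per-node coefficient arrays shared by the transient and steady solvers.
# Volumetric coefficients (heat capacity, perfusion, sources) are weighted by
# the control volume's geometric overlap with each region, so interface nodes
# carry the correct mixed contribution and the MNP source integrates to
# exactly the injection-sphere power.
.bioheat_coeffs <- function(grid, thermal, qmnp) {
  k_node <- .per_node(grid, lapply(thermal, `[[`, "thermal_conductivity"))
  per_region <- function(f, ...) vapply(thermal[colnames(grid$vol_region)], f, 0, ...)
  wV <- function(vals) as.vector(grid$vol_region %*% vals)  # integral over CV
  rhoC_V <- wV(per_region(function(p) p$density * p$specific_heat))
  beta_V <- wV(per_region(function(p)
    p$blood_density * p$blood_specific_heat * p$perfusion_rate))
  qm_V <- wV(per_region(`[[`, "metabolic_heat"))
  alpha_V <- wV(per_region(`[[`, "mnp_source_scale"))
  dr <- diff(grid$r)
  k_face <- 2 * k_node[-grid$n] * k_node[-1] / (k_node[-grid$n] + k_node[-1])
  list(G = grid$face_area * k_face / dr,
       rhoC_V = rhoC_V,
       beta_V = beta_V,
       q_on_V = qm_V + alpha_V * qmnp,
       q_off_V = qm_V,
       Tb = thermal$tumor$arterial_temperature)
}

#' Solve the transient bioheat problem for one AMF exposure
#'
#' Backward-Euler finite-volume integration of the Pennes equation
#' `rho C dT/dt = div(k grad T) + rho_b C_b omega_b (T_b - T) + Q_m + alpha Q_MNP`
#' on the radial grid, with zero flux at the center, a fixed 37 C outer
#' boundary, uniform 37 C initial condition, the MNP source active for
#' `duration` seconds and a cool-down phase afterwards.
#'
#' @param grid a [radial_grid()].
#' @param thermal list of three [tissue_thermal_params()] (`normal`, `tumor`,
#'   `injection`).
#' @param qmnp MNP power density, W/m3 (applied where `mnp_source_scale > 0`);
#'   typically [volumetric_power()].
#' @param duration AMF-on time, s.
#' @param cooldown additional simulated time after switch-off, s.
#' @param dt time step, s.
#' @param t_start absolute time at which heating starts, s (history times are
#'   reported on this clock).
#' @param boundary_temperature outer Dirichlet value, C.
#' @param record_every record the field every this many steps.
#' @return object of class `"temperature_history"`: `times` (s), `T` (matrix,
#'   time x node, C), `probes` data frame (center, injection border, tumor
#'   border), `steady` (steady-state field with the source on), `grid`,
#'   `energy_audit` (relative steady balance residual).
#' @export
solve_bioheat <- function(grid, thermal, qmnp, duration = 3600,
                          cooldown = 5400, dt = 3.6, t_start = 0,
                          boundary_temperature = 37, record_every = 1L) {
  stopifnot(inherits(grid, "radial_grid"), qmnp >= 0, dt > 0)
  co <- .bioheat_coeffs(grid, thermal, qmnp)
  n_on <- max(1L, round(duration / dt))
  n_off <- max(0L, round(cooldown / dt))
  T0 <- rep(37, grid$n)
  on <- .cpp_bioheat_march(T0, co$G, co$rhoC_V, co$beta_V, co$q_on_V,
                           co$Tb, boundary_temperature, dt, n_on,
                           as.integer(record_every))
  Tmat <- on
  t_rec <- t_start + seq(0, by = dt * record_every, length.out = nrow(on))
  if (n_off > 0) {
    off <- .cpp_bioheat_march(on[nrow(on), ], co$G, co$rhoC_V, co$beta_V,
                              co$q_off_V, co$Tb, boundary_temperature, dt,
                              n_off, as.integer(record_every))
    Tmat <- rbind(on, off[-1, , drop = FALSE])
    t_rec <- c(t_rec, t_start + duration +
                 seq_len(nrow(off) - 1L) * dt * record_every)
  }
  steady <- .cpp_bioheat_steady(co$G, co$beta_V, co$q_on_V, co$Tb,
                                boundary_temperature)
  # steady energy balance: source = boundary conduction loss + perfusion sink
  idx <- seq_len(grid$n - 1L)
  src <- sum(co$q_on_V[idx])
  sink <- sum(co$beta_V[idx] * (steady[idx] - co$Tb))
  bflux <- co$G[grid$n - 1L] * (steady[grid$n - 1L] - steady[grid$n])
  audit <- abs(src - sink - bflux) / max(abs(src), 1e-300)

  a <- grid$geometry$injection_radius; b <- grid$geometry$tumor_radius
  i_inj <- which.min(abs(grid$r - a)); i_tum <- which.min(abs(grid$r - b))
  probes <- data.frame(t_s = t_rec,
                       T_center_C = Tmat[, 1],
                       T_injection_border_C = Tmat[, i_inj],
                       T_tumor_border_C = Tmat[, i_tum])
  structure(list(times = t_rec, T = Tmat, probes = probes, steady = steady,
                 grid = grid, dt = dt, amf_duration = duration,
                 energy_audit = audit),
            class = "temperature_history")
}

#' @export
print.temperature_history <- function(x, ...) {
  cat(sprintf("<temperature_history> %d frames over %.2f h; peak center %.2f C, steady center %.2f C\n",
              length(x$times), diff(range(x$times)) / 3600,
              max(x$probes$T_center_C), x$steady[1]))
  invisible(x)
}

#' Steady bioheat field
#'
#' Direct solve of the steady Pennes balance with the MNP source on.
#'
#' @inheritParams solve_bioheat
#' @return numeric vector of nodal temperatures, C.
#' @export
solve_bioheat_steady <- function(grid, thermal, qmnp,
                                 boundary_temperature = 37) {
  co <- .bioheat_coeffs(grid, thermal, qmnp)
  .cpp_bioheat_steady(co$G, co$beta_V, co$q_on_V, co$Tb, boundary_temperature)
}

#' Arrhenius thermal-damage accumulation
#'
#' Trapezoidal accumulation of the damage integral
#' `Omega(r) = integral A exp(-dE / (R T(r, t))) dt` over a temperature
#' history; survival is `DS = exp(-Omega)` and the heat-induced fraction of
#' killed cells is `1 - DS`.
#'
#' @param history a [solve_bioheat()] result, or a list with `times` (s) and
#'   `T` (time x node matrix, C).
#' @param params an [arrhenius_params()].
#' @return object of class `"thermal_damage"`: `omega` (damage integral per
#'   node), `survival` (DS per node), `fkc_heat` (1 - DS per node).
#' @export
arrhenius_survival <- function(history, params = arrhenius_params()) {
  times <- history$times; Tm <- history$T
  stopifnot(length(times) == nrow(Tm))
  rate <- params$frequency_factor *
    exp(-params$activation_energy / (params$gas_constant * (Tm + 273.15)))
  dt <- diff(times)
  w <- c(dt / 2, 0) + c(0, dt / 2)     # trapezoid weights
  omega <- colSums(rate * w)
  ds <- exp(-omega)
  structure(list(omega = omega, survival = ds, fkc_heat = 1 - ds),
            class = "thermal_damage")
}

#' @export
print.thermal_damage <- function(x, ...) {
  cat(sprintf("<thermal_damage> max Omega = %.3g, min survival = %.3g\n",
              max(x$omega), min(x$survival)))
  invisible(x)
}
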