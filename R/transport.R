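# Temperature-coupled four-compartment drug transport: encapsulated carrier
# (CL), free (CF), bound (CB) and internalized (CI) drug on the radial grid.

#' Temperature-dependent release rate from the carrier
#'
#' Piecewise release kinetics: zero below the low threshold (intact liposomes
#' at normothermia), a monotone ramp between the thresholds, and the constant
#' plateau rate at and above the high threshold (the release rate of
#' lysolipid-type TSL is approximately constant once the melting transition
#' is passed).
#'
#' @param temperature temperature(s), C (vectorized).
#' @param drug a [drug_params()].
#' @return release rate K_EL, 1/s.
#' @export
release_rate <- function(temperature, drug = drug_params()) {
  lo <- drug$release_threshold_low; hi <- drug$release_threshold_high
  x <- pmin(pmax((temperature - lo) / (hi - lo), 0), 1)
  shape <- switch(drug$release_ramp,
                  linear = x,
                  exponential = expm1(3 * x) / expm1(3))
  drug$release_rate_at_42 * shape
}

#' Transvascular solute source (Patlak flux)
#'
#' `Phi_B = phi_B (1 - sigma_f) C_p + P S/V (C_p - C) Pe / (exp(Pe) - 1)`
#' with transvascular Peclet number `Pe = phi_B (1 - sigma_f) / (P S/V)`.
#' The Patlak factor tends to 1 as `Pe -> 0` (diffusion-dominated exchange);
#' for a purely convective pathway (`P S/V = 0`) only the filtration term
#' remains. Lymphatic drainage of solute is zero (no functional lymphatics in
#' the tumor).
#'
#' @param cpl plasma concentration, mol/m3.
#' @param c local interstitial concentration, mol/m3.
#' @param phiB fluid filtration rate, 1/s.
#' @param P vessel permeability, m/s.
#' @param sigma_f filtration reflection coefficient.
#' @param sv vessel area density S/V, 1/m.
#' @return volumetric source, mol/(m3 s). All arguments are vectorized.
#' @export
transmural_source <- function(cpl, c, phiB, P, sigma_f, sv) {
  conv <- phiB * (1 - sigma_f)
  psv <- P * sv
  pe <- ifelse(psv > 0, conv / psv, Inf)
  pat <- .patlak(pe)
  conv * cpl + ifelse(psv > 0, psv * (cpl - c) * pat, 0)
}

# Pe / (exp(Pe) - 1), continuous at 0, -> 0 as Pe -> Inf
.patlak <- function(pe) {
  ifelse(!is.finite(pe), 0,
         ifelse(abs(pe) < 1e-8, 1 - pe / 2, pe / expm1(pe)))
}

#' Plasma concentration forcing
#'
#' Mono-exponential decay after a bolus: `C_p(t) = C_p0 exp(-t / k_d)`, with
#' the carrier decay time in `tsl` mode and the minutes-scale free-drug decay
#' time in `free_drug` mode.
#'
#' @param t time since injection, s.
#' @param drug a [drug_params()].
#' @param mode `"tsl"` or `"free_drug"`.
#' @return plasma concentration, mol/m3.
#' @export
plasma_concentration <- function(t, drug = drug_params(),
                                 mode = c("tsl", "free_drug")) {
  mode <- match.arg(mode)
  kd <- if (mode == "tsl") drug$plasma_decay else drug$plasma_decay_free
  drug$initial_plasma_dose * exp(-t / kd)
}

# Face conductances A_f D_f / dr for a per-region diffusivity
.diff_conductance <- function(grid, D_node) {
  dr <- diff(grid$r)
  D_face <- 2 * D_node[-grid$n] * D_node[-1] / (D_node[-grid$n] + D_node[-1])
  grid$face_area * D_face / dr
}

#' Run the coupled drug-transport simulation
#'
#' Marches the four-compartment system over the treatment horizon using
#' operator splitting per step: local kinetics (release, binding,
#' internalization, transvascular exchange) integrated with RK4 substeps and
#' continuous-in-time plasma and release forcing, followed by implicit upwind
#' convection-diffusion of the mobile species. Outer boundary concentration
#' is zero; concentration and flux are continuous across the tumor interface
#' by finite-volume construction.
#'
#' In `tsl` mode the carrier extravasates in the tumor only (hindered-pore
#' closure), released free drug has no transvascular term inside the tumor
#' and is cleared by normal-tissue microvessels; binding and internalization
#' act on tumor cells. In `chemo` mode the carrier is absent and the free
#' drug exchanges with plasma everywhere.
#'
#' @param grid a [radial_grid()].
#' @param flowsol a [solve_ifp()] result.
#' @param drug a [drug_params()].
#' @param flow a [flow_params()] (vessel area density is shared with the
#'   fluid problem).
#' @param mode `"tsl"` or `"chemo"`.
#' @param kel_schedule `NULL` (no release) or a list with `times` (s) and
#'   `mat` (time x node release rate, 1/s), e.g. from a temperature history
#'   via [release_rate()].
#' @param horizon total simulated time, s.
#' @param dt transport time step, s.
#' @param reaction_substeps RK4 substeps of the kinetics per transport step.
#' @param record_every record the tumor averages every this many steps.
#' @param snapshot_times absolute times (s) at which to store full radial
#'   profiles.
#' @param dose_scale multiplier on `drug$initial_plasma_dose`.
#' @param init optional named list of initial nodal fields (`CL`, `CF`, `CB`,
#'   `CI`); compartments default to zero (clean pre-injection state).
#' @return object of class `"drug_history"`: `series` data frame (`t_s`,
#'   `CL_mean`, `CF_mean`, `CB_mean`, `CI_mean`, `fkc_drug`), final fields
#'   `CL`, `CF`, `CB`, `CI`, snapshots, `peaks`, and `mass_audit` (relative
#'   drug mass-balance residual).
#' @export
run_transport <- function(grid, flowsol, drug = drug_params(),
                          flow = flow_params(), mode = c("tsl", "chemo"),
                          kel_schedule = NULL, horizon = 72 * 3600,
                          dt = 3.6, reaction_substeps = 4L,
                          record_every = 100L, snapshot_times = numeric(),
                          dose_scale = 1, init = list()) {
  mode <- match.arg(mode)
  stopifnot(inherits(grid, "radial_grid"), inherits(flowsol, "flow_solution"))
  n <- grid$n
  sv <- flow$vessel_area_density
  tumor <- grid$region %in% c("injection", "tumor")
  normal <- !tumor
  phiB <- flowsol$phiB

  kon <- ifelse(tumor, drug$binding_on * drug$receptor_concentration /
                  drug$accessible_fraction, 0)
  koff <- ifelse(tumor, drug$binding_off / drug$accessible_fraction, 0)
  kint <- ifelse(tumor, drug$internalization, 0)

  zero <- numeric(n)
  if (mode == "tsl") {
    tv <- tsl_vessel_params(drug)
    conv_l <- phiB * (1 - tv$sigma_f_tsl)
    psv_l <- tv$P_tsl * sv
    pat_l <- .patlak(ifelse(psv_l > 0, conv_l / psv_l, Inf))
    exLa <- ifelse(tumor, conv_l + psv_l * pat_l, tv$P_tsl_normal * sv)
    exLl <- ifelse(tumor, psv_l * pat_l, tv$P_tsl_normal * sv)
    # released drug: no transvascular term in the tumor equations; cleared by
    # normal-tissue microvessels (plasma free-drug level ~ 0)
    exFa <- zero
    exFl <- ifelse(normal, drug$vessel_permeability_free * sv, 0)
    kd <- drug$plasma_decay
    mobileL <- TRUE
  } else {
    conv_f <- phiB * (1 - drug$filtration_reflection_free)
    psv_f <- drug$vessel_permeability_free * sv
    pat_f <- .patlak(ifelse(psv_f > 0, conv_f / psv_f, Inf))
    exFa <- conv_f + psv_f * pat_f
    exFl <- rep(psv_f, n) * ifelse(tumor, pat_f, 1)
    exFa[normal] <- psv_f
    exLa <- zero; exLl <- zero
    kd <- drug$plasma_decay_free
    mobileL <- FALSE
  }

  G_L <- .diff_conductance(grid, rep(drug$tsl_diffusivity, n))
  G_F <- .diff_conductance(grid, rep(drug$free_drug_diffusivity, n))
  conv_face <- grid$face_area * flowsol$u_face

  nsteps <- max(1L, round(horizon / dt))
  if (is.null(kel_schedule))
    kel_schedule <- list(times = c(0, horizon), mat = matrix(0, 2, n))
  snap_steps <- sort(unique(pmin(pmax(round(snapshot_times / dt), 1L), nsteps)))

  w_tumor <- grid$vol_region[, "injection"] + grid$vol_region[, "tumor"]
  init <- modifyList(list(CL = zero, CF = zero, CB = zero, CI = zero), init)
  res <- .cpp_transport_march(list(
    CL0 = init$CL, CF0 = init$CF, CB0 = init$CB, CI0 = init$CI,
    dt = dt, nsteps = as.integer(nsteps), nsub = as.integer(reaction_substeps),
    t0 = 0,
    volume = grid$volume, G_L = G_L, G_F = G_F, conv = conv_face,
    mobileL = mobileL, kon = kon, koff = koff, kint = kint,
    exLa = exLa, exLl = exLl, exFa = exFa, exFl = exFl,
    cp0 = drug$initial_plasma_dose * dose_scale, kd = kd,
    kel_times = kel_schedule$times, kel_mat = kel_schedule$mat,
    w_tumor = w_tumor, omega = drug$survival_constant,
    record_every = as.integer(record_every),
    snapshot_steps = as.integer(snap_steps)))

  audit <- abs(res$mass_total - res$mass_initial - (res$influx - res$outflux)) /
    max(res$influx, res$mass_initial, 1e-300)
  if (is.finite(audit) && audit > 0.005)
    stop(sprintf("drug mass-balance drift %.3g exceeds 0.5%%", audit),
         call. = FALSE)

  series <- data.frame(t_s = res$times, CL_mean = res$CL_mean,
                       CF_mean = res$CF_mean, CB_mean = res$CB_mean,
                       CI_mean = res$CI_mean,
                       fkc_drug = 1 - res$drug_survival_mean)
  pk <- function(v) {
    i <- which.max(v); c(value = v[i], t_s = res$times[i])
  }
  peaks <- rbind(CL = pk(res$CL_mean), CF = pk(res$CF_mean),
                 CB = pk(res$CB_mean), CI = pk(res$CI_mean))
  structure(list(series = series, CL = res$CL, CF = res$CF, CB = res$CB,
                 CI = res$CI, peaks = as.data.frame(peaks),
                 snapshots = list(t_s = res$snap_t, CL = res$snapCL,
                                  CF = res$snapCF, CB = res$snapCB,
                                  CI = res$snapCI),
                 mass_audit = audit, mode = mode, grid = grid),
            class = "drug_history")
}

#' @export
print.drug_history <- function(x, ...) {
  cat(sprintf("<drug_history> mode %s; peak mean CI %.3g mol/m3 at %.1f h; mass residual %.2g\n",
              x$mode, x$peaks["CI", "value"], x$peaks["CI", "t_s"] / 3600,
              x$mass_audit))
  invisible(x)
}
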