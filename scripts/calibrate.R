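#!/usr/bin/env Rscript
# Calibration of the unprinted model constants, in two stages. The resulting
# values are frozen as package defaults and documented in the methods
# vignette; re-run this script to reproduce them.
#
# Stage 1 (thermal): the MNP anisotropy constant Keff is the designated knob
# mapping the linear-response power to the observed heating; with perfusion
# fixed at the documented low-perfusion value it is solved so the 60-min,
# 11 kA/m exposure reaches 42.2 C at the center of the injection site.
#
# Stage 2 (drug): the carrier plasma decay time kd, the unhindered-pathway
# permeability scale P_ref and the pore-size geometric spread gsd are fitted
# against the tumor uptake/efficacy observables of the combination scenario
# (peak tumor-mean internalized concentration 1.2 mol/m3; 48-h-delay FKC
# 0.21; 100 vs 200 nm pore FKC contrast 0.42/0.52). A single mono-exponential
# plasma model cannot simultaneously reproduce these and a 9-h tumor carrier
# peak; the uptake/efficacy observables take precedence (see the vignette).
#
# Usage: Rscript scripts/calibrate.R  (several minutes)

suppressPackageStartupMessages(library(thermodox))

geom <- list(injection_radius = 2.5e-3, tumor_radius = 1e-2, outer_radius = 3e-2)
grid <- radial_grid(geom)
thermal <- list(
  normal = tissue_thermal_params(1060, 3600, 0.59, perfusion_rate = 5e-5),
  tumor = tissue_thermal_params(1040, 3600, 0.57, perfusion_rate = 5e-5),
  injection = tissue_thermal_params(5180, 670, 528, perfusion_rate = 5e-5,
                                    mnp_source_scale = 1))

## ---- Stage 1: Keff ----
probes_60min <- function(keff) {
  q <- volumetric_power(magnetic_spec(anisotropy_constant = keff),
                        field_spec(amplitude = 11e3))
  h <- solve_bioheat(grid, thermal, q, duration = 3600, cooldown = 0, dt = 3.6)
  i <- nrow(h$T)
  c(center = h$T[i, 1], border = h$T[i, which.min(abs(grid$r - 1e-2))])
}
# joint equal-error calibration against the printed (42.2, 38.5) C pair:
# a single amplitude knob cannot hit both exactly (the border/center rise
# ratio is geometry-limited), so Keff balances the two residuals
keff <- uniroot(function(k) {
  p <- probes_60min(k); (p["center"] - 42.2) - (38.5 - p["border"])
}, c(3e4, 5e4), tol = 0.5)$root
p <- probes_60min(keff)
cat(sprintf("Stage 1: Keff = %.0f J/m3 (center %.3f C, border %.3f C)\n",
            keff, p["center"], p["border"]))

## ---- Stage 2: kd, P_ref, gsd ----
base <- scenario_preset("combo_9h")
base$solver$dt_transport <- 7.2
with_drug <- function(kd_h, pref, gsd, pore = 200e-9) {
  d <- unclass(base$drug)
  d$plasma_decay <- kd_h * 3600
  d$pore_reference_permeability <- pref
  d$pore_gsd <- gsd
  d$vessel_pore_diameter <- pore
  cfg <- base
  cfg$drug <- do.call(drug_params, d[names(formals(drug_params))])
  cfg
}
objective <- function(kd_h, pref, gsd) {
  r <- run_scenario(with_drug(kd_h, pref, gsd))
  d48 <- run_sweep(with_drug(kd_h, pref, gsd), axis = "delay",
                   values = 48 * 3600, horizon_policy = "extend")
  p100 <- run_scenario(with_drug(kd_h, pref, gsd, pore = 100e-9))
  d15 <- run_scenario(with_drug(kd_h, pref, gsd), dose_scale = 1.5)
  obs <- c(ci = r$drug$peaks["CI", "value"],
           combined = r$efficacy$fkc_combined,
           fkc48 = d48$summary$fkc_combined[1],
           dose15 = d15$efficacy$fkc_combined,
           pore_ratio = p100$efficacy$fkc_drug / r$efficacy$fkc_drug)
  # the peak concentration has a wide reported band (~20%); treat it as a
  # constraint and fit the four efficacy observables by least squares
  tgt <- c(combined = 0.50, fkc48 = 0.21, dose15 = 0.63,
           pore_ratio = 0.42 / 0.52)
  feasible <- abs(obs["ci"] - 1.2) <= 0.2 * 1.2
  list(obs = obs,
       err = sum((obs[names(tgt)] - tgt)^2) + ifelse(feasible, 0, Inf))
}
cand <- expand.grid(kd_h = c(24, 30, 36),
                    pref = c(1.4e-7, 1.8e-7, 2.2e-7),
                    gsd = c(2.0, 2.2))
cand$err <- NA
for (i in seq_len(nrow(cand))) {
  o <- objective(cand$kd_h[i], cand$pref[i], cand$gsd[i])
  cand$err[i] <- o$err
  cat(sprintf("kd=%2.0f h  P_ref=%.2e  gsd=%.1f  ->  CI %.2f, comb %.3f, FKC(48h) %.3f, 1.5x %.3f, pore ratio %.2f  (err %.3f)\n",
              cand$kd_h[i], cand$pref[i], cand$gsd[i], o$obs["ci"],
              o$obs["combined"], o$obs["fkc48"], o$obs["dose15"],
              o$obs["pore_ratio"], o$err))
}
best <- cand[which.min(cand$err), ]
cat(sprintf("Stage 2: kd = %.0f h, P_ref = %.2e m/s, gsd = %.1f\n",
            best$kd_h, best$pref, best$gsd))
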