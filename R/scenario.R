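# Scenario orchestration: steady flow -> AMF heating -> drug transport ->
# pharmacodynamics, plus sweeps over treatment parameters.

#' Run a full treatment scenario
#'
#' Executes the pipeline for one configured scenario: steady interstitial
#' flow; transient MNP heating and Arrhenius damage over the AMF window
#' (starting `delay` seconds after carrier injection); temperature-coupled
#' drug transport over the full horizon; and the terminal kill decomposition.
#' Modes: `"chemo"` (free-drug bolus, no heating), `"mht_only"` (heating
#' only, no drug), `"combination"` (TSL bolus + triggered release).
#'
#' @param config a [scenario_config()].
#' @param dose_scale multiplier on the configured initial plasma dose
#'   (used by the dose sweep).
#' @param .flow,.heat optional precomputed stage results (sweep caching).
#' @return object of class `"scenario_result"` with elements `config`,
#'   `grid`, `flow`, `temperature`, `damage`, `drug`, `efficacy`, `qmnp`,
#'   `audits` and `provenance`.
#' @export
run_scenario <- function(config, dose_scale = 1, .flow = NULL, .heat = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  sch <- config$schedule; sol <- config$solver
  if (!is.null(sol$seed)) set.seed(sol$seed)
  grid <- radial_grid(config$geometry,
                      n = c(sol$n_injection, sol$n_tumor, sol$n_normal))
  mode <- sch$mode

  flow <- NULL; heat <- NULL; damage <- NULL; drug_hist <- NULL
  qmnp <- 0
  ds_field <- rep(1, grid$n)

  if (mode != "mht_only") {
    flow <- if (is.null(.flow)) solve_ifp(grid, config$flow) else .flow
  }

  if (mode != "chemo") {
    qmnp <- volumetric_power(config$magnetic, config$field)
    heat <- if (is.null(.heat)) {
      solve_bioheat(grid, config$thermal, qmnp,
                    duration = sch$amf_duration, cooldown = sol$cooldown,
                    dt = sol$dt_thermal, t_start = sch$delay)
    } else .heat
    if (!is.null(.heat) && abs(heat$times[1] - sch$delay) > 1e-9) {
      shift <- sch$delay - heat$times[1]
      heat$times <- heat$times + shift
      heat$probes$t_s <- heat$probes$t_s + shift
    }
    damage <- arrhenius_survival(heat, config$arrhenius)
    ds_field <- damage$survival
  }

  if (mode != "mht_only") {
    kel <- NULL
    if (mode == "combination") {
      kel <- list(times = heat$times,
                  mat = release_rate(heat$T, config$drug))
    }
    snap_times <- unique(pmin(
      c(sch$delay + sch$amf_duration, 24 * 3600, 48 * 3600, sch$horizon),
      sch$horizon))
    drug_hist <- run_transport(
      grid, flow, drug = config$drug, flow = config$flow,
      mode = if (mode == "chemo") "chemo" else "tsl",
      kel_schedule = kel, horizon = sch$horizon, dt = sol$dt_transport,
      reaction_substeps = sol$reaction_substeps,
      record_every = max(1L, round(sch$checkpoint / sol$dt_transport)),
      snapshot_times = snap_times, dose_scale = dose_scale)
  }

  ci_field <- if (is.null(drug_hist)) rep(0, grid$n) else drug_hist$CI
  eff <- combine_kill(ds_field, ci_field, grid,
                      omega = config$drug$survival_constant)

  audits <- list(
    thermal_energy = if (is.null(heat)) NA_real_ else heat$energy_audit,
    flow_mass = if (is.null(flow)) NA_real_ else flow$mass_balance,
    drug_mass = if (is.null(drug_hist)) NA_real_ else drug_hist$mass_audit)

  structure(list(config = config, grid = grid, flow = flow,
                 temperature = heat, damage = damage, drug = drug_hist,
                 efficacy = eff, qmnp = qmnp, dose_scale = dose_scale,
                 audits = audits,
                 provenance = list(
                   package = "thermodox",
                   version = as.character(utils::packageVersion("thermodox")))),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result> mode:", x$config$schedule$mode, "\n")
  if (!is.null(x$temperature)) {
    cat(sprintf("  heating: Q_MNP = %.3g W/m3; end-of-AMF center %.2f C, tumor border %.2f C\n",
                x$qmnp, .temp_at_end_of_amf(x)["center"],
                .temp_at_end_of_amf(x)["tumor_border"]))
  }
  if (!is.null(x$drug))
    cat(sprintf("  drug: peak mean CI %.3g mol/m3 at %.1f h post-injection\n",
                x$drug$peaks["CI", "value"], x$drug$peaks["CI", "t_s"] / 3600))
  e <- x$efficacy
  cat(sprintf("  FKC: heat %.1f%%, drug %.1f%%, combined %.1f%%\n",
              100 * e$fkc_heat, 100 * e$fkc_drug, 100 * e$fkc_combined))
  invisible(x)
}

# probe temperatures at the end of the AMF-on window
.temp_at_end_of_amf <- function(result) {
  h <- result$temperature
  t_end <- h$times[1] + h$amf_duration
  i <- which.min(abs(h$times - t_end))
  c(center = h$probes$T_center_C[i],
    injection_border = h$probes$T_injection_border_C[i],
    tumor_border = h$probes$T_tumor_border_C[i])
}

#' @export
summary.scenario_result <- function(object, ...) {
  e <- object$efficacy
  out <- list(mode = object$config$schedule$mode,
              fkc_heat = e$fkc_heat, fkc_drug = e$fkc_drug,
              fkc_combined = e$fkc_combined,
              decomposition = e$decomposition,
              qmnp_w_m3 = object$qmnp)
  if (!is.null(object$temperature)) {
    out$temperature_end_of_amf <- .temp_at_end_of_amf(object)
    out$time_to_plateau_s <- time_to_plateau(object$temperature)
  }
  if (!is.null(object$drug)) {
    out$peak_mean_ci <- object$drug$peaks["CI", "value"]
    out$peak_mean_ci_t_h <- object$drug$peaks["CI", "t_s"] / 3600
    out$peak_mean_cl_t_h <- object$drug$peaks["CL", "t_s"] / 3600
  }
  out$audits <- object$audits
  class(out) <- "summary.scenario_result"
  out
}

#' @export
print.summary.scenario_result <- function(x, ...) {
  cat("Scenario mode:", x$mode, "\n")
  cat(sprintf("FKC heat/drug/combined: %.3f / %.3f / %.3f\n",
              x$fkc_heat, x$fkc_drug, x$fkc_combined))
  if (!is.null(x$temperature_end_of_amf))
    cat(sprintf("End-of-AMF temperatures (C): center %.2f, injection border %.2f, tumor border %.2f\n",
                x$temperature_end_of_amf["center"],
                x$temperature_end_of_amf["injection_border"],
                x$temperature_end_of_amf["tumor_border"]))
  if (!is.null(x$peak_mean_ci))
    cat(sprintf("Peak tumor-mean internalized drug: %.3g mol/m3 at %.1f h\n",
                x$peak_mean_ci, x$peak_mean_ci_t_h))
  invisible(x)
}

#' Time for the center temperature to plateau
#'
#' Time from AMF start until the center temperature first reaches the given
#' fraction of its steady rise.
#'
#' @param history a [solve_bioheat()] result.
#' @param fraction fraction of the steady temperature rise (default 0.99).
#' @return time, s.
#' @export
time_to_plateau <- function(history, fraction = 0.99) {
  rise <- history$probes$T_center_C - history$probes$T_center_C[1]
  target <- fraction * (history$steady[1] - history$probes$T_center_C[1])
  on <- history$times - history$times[1] <= history$amf_duration
  i <- which(rise[on] >= target)[1]
  if (is.na(i)) return(NA_real_)
  history$times[i] - history$times[1]
}

#' @export
plot.scenario_result <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  if (!is.null(x$temperature)) {
    p <- x$temperature$probes
    graphics::matplot((p$t_s - p$t_s[1]) / 60,
                      p[, c("T_center_C", "T_injection_border_C", "T_tumor_border_C")],
                      type = "l", lty = 1, xlab = "minutes from AMF start",
                      ylab = "T (C)", main = "Temperature probes")
    graphics::legend("right", c("center", "injection border", "tumor border"),
                     col = 1:3, lty = 1, bty = "n", cex = 0.8)
  } else graphics::plot.new()
  if (!is.null(x$drug)) {
    s <- x$drug$series
    graphics::matplot(s$t_s / 3600, s[, c("CL_mean", "CF_mean", "CB_mean", "CI_mean")],
                      type = "l", lty = 1, xlab = "hours post-injection",
                      ylab = "mol/m3", main = "Tumor-mean concentrations")
    graphics::legend("topright", c("TSL", "free", "bound", "internalized"),
                     col = 1:4, lty = 1, bty = "n", cex = 0.8)
    graphics::plot(s$t_s / 3600, s$fkc_drug, type = "l",
                   xlab = "hours post-injection", ylab = "FKC (drug)",
                   main = "Drug-induced kill")
    graphics::plot(x$grid$r * 100, x$drug$CI, type = "l", xlab = "r (cm)",
                   ylab = "CI (mol/m3)", main = "Terminal internalized drug")
  }
  invisible(x)
}

#' Sweep a treatment parameter across values
#'
#' Re-runs the scenario along one axis, reusing stages the axis does not
#' affect (the steady flow field for all axes; the heating stage for axes
#' that do not change the field).
#'
#' @param config base [scenario_config()].
#' @param axis one of `"delay"` (s), `"dose"` (multiplier on Cp0),
#'   `"pore_size"` (m), `"field_amplitude"` (A/m).
#' @param values numeric values along the axis.
#' @param horizon_policy `"fixed"` keeps the configured horizon;
#'   `"extend"` (delay axis) keeps the post-AMF observation window equal to
#'   the base configuration's.
#' @return object of class `"scenario_sweep"`: `summary` data frame and the
#'   list of full results.
#' @export
run_sweep <- function(config, axis = c("delay", "dose", "pore_size",
                                       "field_amplitude"),
                      values, horizon_policy = c("fixed", "extend")) {
  axis <- match.arg(axis)
  horizon_policy <- match.arg(horizon_policy)
  stopifnot(length(values) >= 1L)
  sol <- config$solver
  grid <- radial_grid(config$geometry,
                      n = c(sol$n_injection, sol$n_tumor, sol$n_normal))
  flow_cache <- if (config$schedule$mode != "mht_only")
    solve_ifp(grid, config$flow) else NULL
  heat_cache <- NULL
  if (config$schedule$mode != "chemo" && axis != "field_amplitude") {
    qmnp <- volumetric_power(config$magnetic, config$field)
    heat_cache <- solve_bioheat(grid, config$thermal, qmnp,
                                duration = config$schedule$amf_duration,
                                cooldown = sol$cooldown,
                                dt = sol$dt_thermal,
                                t_start = config$schedule$delay)
  }
  post_window <- config$schedule$horizon - config$schedule$delay -
    config$schedule$amf_duration

  results <- vector("list", length(values))
  rows <- vector("list", length(values))
  for (i in seq_along(values)) {
    v <- values[[i]]
    res <- tryCatch({
      cfg <- config; dscale <- 1
      if (axis == "delay") {
        cfg$schedule$delay <- v
        if (horizon_policy == "extend")
          cfg$schedule$horizon <- v + cfg$schedule$amf_duration + post_window
      } else if (axis == "dose") {
        dscale <- v
      } else if (axis == "pore_size") {
        d <- unclass(cfg$drug); d$vessel_pore_diameter <- v
        cfg$drug <- do.call(drug_params, d[names(formals(drug_params))])
      } else if (axis == "field_amplitude") {
        f <- unclass(cfg$field); f$amplitude <- v
        cfg$field <- do.call(field_spec, f[names(formals(field_spec))])
      }
      run_scenario(cfg, dose_scale = dscale, .flow = flow_cache,
                   .heat = heat_cache)
    }, error = function(e) e)
    results[[i]] <- res
    rows[[i]] <- if (inherits(res, "error")) {
      data.frame(value = v, fkc_heat = NA, fkc_drug = NA, fkc_combined = NA,
                 peak_mean_ci = NA, error = conditionMessage(res))
    } else {
      data.frame(value = v,
                 fkc_heat = res$efficacy$fkc_heat,
                 fkc_drug = res$efficacy$fkc_drug,
                 fkc_combined = res$efficacy$fkc_combined,
                 peak_mean_ci = if (is.null(res$drug)) 0 else
                   res$drug$peaks["CI", "value"],
                 error = NA_character_)
    }
  }
  structure(list(axis = axis, summary = do.call(rbind, rows),
                 results = results),
            class = "scenario_sweep")
}

#' @export
print.scenario_sweep <- function(x, ...) {
  cat("<scenario_sweep> axis:", x$axis, "\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Built-in scenario presets
#'
#' Named preset configurations shipped as YAML documents under
#' `inst/scenarios/`: `chemo_baseline`, `mht_11kAm`, `mht_13kAm`, `combo_9h`.
#'
#' @param name preset name; with no argument, lists available presets.
#' @return a [scenario_config()], or a character vector of names.
#' @export
scenario_preset <- function(name = NULL) {
  dir <- system.file("scenarios", package = "thermodox")
  avail <- sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$"))
  if (is.null(name)) return(avail)
  path <- file.path(dir, paste0(name, ".yaml"))
  if (!file.exists(path))
    stop("unknown preset `", name, "`; available: ",
         paste(avail, collapse = ", "), call. = FALSE)
  load_scenario(path)
}

#' MNP power diagnostics for a configuration
#'
#' Relaxation times, susceptibility and dissipated power density for the
#' configured particle/field pair (the quantities one calibrates against
#' measured heating curves).
#'
#' @param config a [scenario_config()].
#' @param Ts evaluation temperature, K.
#' @return one-row data frame.
#' @export
mnp_power_table <- function(config, Ts = 310.15) {
  rt <- relaxation_times(config$magnetic, Ts)
  chi0 <- equilibrium_susceptibility(config$magnetic, config$field, Ts)
  data.frame(tau_B_s = rt$brown, tau_N_s = rt$neel, tau_eff_s = rt$effective,
             anisotropy_ratio = rt$anisotropy_ratio, chi0 = chi0,
             qmnp_w_m3 = volumetric_power(config$magnetic, config$field, Ts))
}

#' Write scenario outputs to a directory
#'
#' Serializes a result the way the command-line interface does:
#' `summary.json`, `timeseries.csv`, `profiles/*.csv` and
#' `resolved_config.yaml`.
#'
#' @param result a [run_scenario()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario_outputs <- function(result, dir) {
  stopifnot(inherits(result, "scenario_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "profiles"), showWarnings = FALSE)
  s <- summary(result)
  jsonlite::write_json(unclass(s), file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  if (!is.null(result$drug))
    utils::write.csv(result$drug$series, file.path(dir, "timeseries.csv"),
                     row.names = FALSE)
  if (!is.null(result$temperature))
    utils::write.csv(result$temperature$probes,
                     file.path(dir, "temperature_probes.csv"),
                     row.names = FALSE)
  prof <- data.frame(r_m = result$grid$r, region = result$grid$region)
  if (!is.null(result$flow)) {
    prof$p_mmHg <- result$flow$p_mmHg
    prof$u_m_per_s <- result$flow$u_node
    prof$phiB_per_s <- result$flow$phiB
  }
  if (!is.null(result$damage)) prof$heat_survival <- result$damage$survival
  if (!is.null(result$drug)) {
    prof$CL <- result$drug$CL; prof$CF <- result$drug$CF
    prof$CB <- result$drug$CB; prof$CI <- result$drug$CI
  }
  utils::write.csv(prof, file.path(dir, "profiles", "radial_profiles.csv"),
                   row.names = FALSE)
  scenario_to_yaml(result$config, file.path(dir, "resolved_config.yaml"))
  invisible(dir)
}
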