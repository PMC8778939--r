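#' @useDynLib thermodox, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx qnorm setNames
#' @importFrom utils modifyList
NULL

# Physical constants used across the solvers
.kB   <- 1.380649e-23   # Boltzmann constant, J/K
.MU0  <- 4 * pi * 1e-7  # vacuum permeability, H/m

.check_pos <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) stop("invariant violated: `", name, "` must be ",
                if (strict) "strictly positive" else "non-negative",
                call. = FALSE)
  invisible(x)
}

.check_frac <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop("invariant violated: `", name, "` must lie in `[0, 1]`", call. = FALSE)
  invisible(x)
}

#' Thermal parameters of one tissue region
#'
#' One instance per region of the nested geometry (normal tissue, tumor,
#' MNP-laden injection site). Material properties of the three regions follow
#' the standard three-material parameterization of MNP hyperthermia models:
#' the injection site carries the properties of the ferrofluid-saturated
#' region (magnetite-dominated density, conductivity and specific heat), which
#' renders it nearly isothermal during heating.
#'
#' Perfusion, blood properties and metabolic heat are not part of the material
#' table; defaults are standard Pennes-model literature values and are exposed
#' here for calibration (see the methods vignette).
#'
#' @param density tissue density rho, kg/m3.
#' @param specific_heat tissue specific heat C, J/(kg C).
#' @param thermal_conductivity k, W/(m C).
#' @param blood_density rho_b, kg/m3.
#' @param blood_specific_heat C_b, J/(kg C).
#' @param perfusion_rate blood perfusion rate omega_b, 1/s.
#' @param arterial_temperature T_b, degrees C.
#' @param metabolic_heat Q_m, W/m3 (>= 0).
#' @param mnp_source_scale alpha in the bioheat source term `alpha * Q_MNP`;
#'   an indicator/scale of MNP presence (1 inside the injection region, 0
#'   elsewhere).
#' @return object of class `"tissue_thermal_params"`.
#' @export
tissue_thermal_params <- function(density,
                                  specific_heat,
                                  thermal_conductivity,
                                  blood_density = 1000,
                                  blood_specific_heat = 3600,
                                  perfusion_rate = 5e-4,
                                  arterial_temperature = 37,
                                  metabolic_heat = 420,
                                  mnp_source_scale = 0) {
  .check_pos(density, "density")
  .check_pos(specific_heat, "specific_heat")
  .check_pos(thermal_conductivity, "thermal_conductivity")
  .check_pos(blood_density, "blood_density")
  .check_pos(blood_specific_heat, "blood_specific_heat")
  .check_pos(perfusion_rate, "perfusion_rate", strict = FALSE)
  .check_pos(arterial_temperature, "arterial_temperature")
  .check_pos(metabolic_heat, "metabolic_heat", strict = FALSE)
  .check_frac(mnp_source_scale, "mnp_source_scale")
  structure(list(
    density = density, specific_heat = specific_heat,
    thermal_conductivity = thermal_conductivity,
    blood_density = blood_density, blood_specific_heat = blood_specific_heat,
    perfusion_rate = perfusion_rate,
    arterial_temperature = arterial_temperature,
    metabolic_heat = metabolic_heat, mnp_source_scale = mnp_source_scale),
    class = "tissue_thermal_params")
}

# Region defaults: material table of the three-region geometry.
# Tumor perfusion defaults reflect the poorly perfused solid-tumor core; both
# perfusion values are calibration-exposed (see scripts/calibrate.R and the
# methods vignette).
.default_thermal <- function() {
  list(
    normal = tissue_thermal_params(
      density = 1060, specific_heat = 3600, thermal_conductivity = 0.59,
      perfusion_rate = 5e-5, mnp_source_scale = 0),
    tumor = tissue_thermal_params(
      density = 1040, specific_heat = 3600, thermal_conductivity = 0.57,
      perfusion_rate = 5e-5, mnp_source_scale = 0),
    injection = tissue_thermal_params(
      density = 5180, specific_heat = 670, thermal_conductivity = 528,
      perfusion_rate = 5e-5, mnp_source_scale = 1)
  )
}

#' Magnetic nanoparticle suspension specification
#'
#' Single-domain superparamagnetic iron-oxide particles; the superparamagnetic
#' regime restricts the core diameter to at most 20 nm (hysteresis losses are
#' negligible below that size and relaxation losses dominate).
#'
#' @param core_diameter magnetic core diameter, m (<= 20e-9).
#' @param coating_thickness nonmagnetic coating thickness, m.
#' @param volume_fraction MNP volume fraction phi of the ferrofluid in the
#'   injection region (0 < phi < 1).
#' @param anisotropy_constant K_eff, J/m3. Magnetite nanoparticles span roughly
#'   1e4-4e4 J/m3; the default is the calibrated value documented in the
#'   methods vignette.
#' @param domain_magnetization M_d, A/m (default 446 kA/m, magnetite).
#' @param attempt_time tau_0, s (default 1e-9).
#' @param suspension_viscosity delta, Pa s (default 1e-3, water-based).
#' @param particle_density,particle_specific_heat,particle_conductivity bulk
#'   magnetite properties (used for the injection-region material).
#' @return object of class `"magnetic_spec"`.
#' @export
magnetic_spec <- function(core_diameter = 10e-9,
                          coating_thickness = 0,
                          volume_fraction = 0.033,
                          anisotropy_constant = 37025,
                          domain_magnetization = 446e3,
                          attempt_time = 1e-9,
                          suspension_viscosity = 1e-3,
                          particle_density = 5180,
                          particle_specific_heat = 670,
                          particle_conductivity = 528) {
  .check_pos(core_diameter, "core_diameter")
  if (core_diameter > 20e-9)
    stop("invariant violated: `core_diameter` must be <= 20 nm ",
         "(superparamagnetic single-domain regime)", call. = FALSE)
  .check_pos(coating_thickness, "coating_thickness", strict = FALSE)
  if (volume_fraction <= 0 || volume_fraction >= 1)
    stop("invariant violated: `volume_fraction` must lie in (0, 1)", call. = FALSE)
  .check_pos(anisotropy_constant, "anisotropy_constant")
  .check_pos(domain_magnetization, "domain_magnetization")
  .check_pos(attempt_time, "attempt_time")
  .check_pos(suspension_viscosity, "suspension_viscosity")
  spec <- structure(list(
    core_diameter = core_diameter, coating_thickness = coating_thickness,
    volume_fraction = volume_fraction,
    anisotropy_constant = anisotropy_constant,
    domain_magnetization = domain_magnetization,
    attempt_time = attempt_time, suspension_viscosity = suspension_viscosity,
    particle_density = particle_density,
    particle_specific_heat = particle_specific_heat,
    particle_conductivity = particle_conductivity),
    class = "magnetic_spec")
  vm <- magnetic_volume(spec); vh <- hydrodynamic_volume(spec)
  stopifnot(vm > 0, vh >= vm)
  spec
}

#' @rdname magnetic_spec
#' @param spec a `magnetic_spec`.
#' @export
magnetic_volume <- function(spec) pi / 6 * spec$core_diameter^3

#' @rdname magnetic_spec
#' @export
hydrodynamic_volume <- function(spec)
  pi / 6 * (spec$core_diameter + 2 * spec$coating_thickness)^3

#' Alternating magnetic field specification
#'
#' The product `amplitude * frequency` is compared against a configurable
#' safety bound (the commonly cited clinical tolerance limit of
#' 5e9 A/(m s)); exceeding it is a validation error unless the limit is
#' raised explicitly.
#'
#' @param amplitude field amplitude H_m, A/m.
#' @param frequency field frequency f, Hz.
#' @param on_time AMF exposure duration per application, s.
#' @param off_time time between applications, s (must exceed `on_time`).
#' @param safety_product_limit maximum allowed `amplitude * frequency`,
#'   A/(m s).
#' @return object of class `"field_spec"`.
#' @export
field_spec <- function(amplitude = 11e3,
                       frequency = 400e3,
                       on_time = 3600,
                       off_time = Inf,
                       safety_product_limit = 5e9) {
  .check_pos(amplitude, "amplitude", strict = FALSE)
  .check_pos(frequency, "frequency", strict = FALSE)
  .check_pos(on_time, "on_time")
  if (!(on_time < off_time))
    stop("invariant violated: `on_time` must be smaller than `off_time`",
         call. = FALSE)
  if (amplitude * frequency > safety_product_limit)
    stop("invariant violated: field safety product H*f = ",
         format(amplitude * frequency, digits = 3),
         " A/(m s) exceeds `safety_product_limit` = ",
         format(safety_product_limit, digits = 3),
         "; raise the limit explicitly to allow this exposure", call. = FALSE)
  structure(list(amplitude = amplitude, frequency = frequency,
                 vacuum_permeability = .MU0,
                 on_time = on_time, off_time = off_time,
                 safety_product_limit = safety_product_limit),
            class = "field_spec")
}

#' Arrhenius thermal-damage kinetics parameters
#'
#' First-order thermal kill with survival `DS = exp(-Omega)`,
#' `Omega = integral of A * exp(-dE / (R T(t))) dt` (T in kelvin).
#'
#' @param frequency_factor A, 1/s.
#' @param activation_energy dE, J/mol.
#' @param gas_constant R, J/(mol K).
#' @return object of class `"arrhenius_params"`.
#' @export
arrhenius_params <- function(frequency_factor = 1.98e106,
                             activation_energy = 6.67e5,
                             gas_constant = 8.314) {
  .check_pos(frequency_factor, "frequency_factor")
  .check_pos(activation_energy, "activation_energy")
  .check_pos(gas_constant, "gas_constant")
  structure(list(frequency_factor = frequency_factor,
                 activation_energy = activation_energy,
                 gas_constant = gas_constant),
            class = "arrhenius_params")
}

#' Interstitial flow (Darcy-Starling) parameters
#'
#' Defaults are the standard interstitial transport property set for solid
#' tumors; all values are stored in SI (conversions from the conventional
#' cm/mmHg units happen at construction or at the YAML boundary).
#'
#' @param hydraulic_conductivity interstitium hydraulic conductivity kappa,
#'   m2/(Pa s). Default is 4.13e-8 cm2/(mmHg s).
#' @param vessel_hydraulic_conductivity vessel-wall hydraulic conductivity
#'   L_p, m/(Pa s). Default is 2.8e-7 cm/(mmHg s).
#' @param vessel_area_density vascular surface area per unit volume S/V, 1/m.
#' @param vascular_pressure P_b, Pa (default 15.6 mmHg).
#' @param plasma_osmotic_pressure pi_B, Pa (default 20 mmHg).
#' @param interstitial_osmotic_pressure pi_i, Pa (default 15 mmHg).
#' @param osmotic_reflection sigma_s in `[0, 1]`.
#' @param lymph_drainage phi_L, 1/s; zero inside the tumor (no functional
#'   lymphatics).
#' @param starling_normal normal-tissue fluid handling: `"sink"` (default,
#'   lymphatic drainage `L_p S/V p` absorbs the tumor filtrate in a thin
#'   peritumoral layer, giving the steep experimental IFP drop at the tumor
#'   edge), `"balanced"` (no net source or sink) or `"full"` (Starling
#'   source also in normal tissue). See [solve_ifp()].
#' @return object of class `"flow_params"`.
#' @export
flow_params <- function(hydraulic_conductivity = convert_units(4.13e-8, "cm2_per_mmHg_s", "m2_per_Pa_s"),
                        vessel_hydraulic_conductivity = convert_units(2.8e-7, "cm_per_mmHg_s", "m_per_Pa_s"),
                        vessel_area_density = 2e4,
                        vascular_pressure = convert_units(15.6, "mmHg", "Pa"),
                        plasma_osmotic_pressure = convert_units(20, "mmHg", "Pa"),
                        interstitial_osmotic_pressure = convert_units(15, "mmHg", "Pa"),
                        osmotic_reflection = 0.82,
                        lymph_drainage = 0,
                        starling_normal = c("sink", "balanced", "full")) {
  .check_pos(hydraulic_conductivity, "hydraulic_conductivity")
  .check_pos(vessel_hydraulic_conductivity, "vessel_hydraulic_conductivity",
             strict = FALSE)
  .check_pos(vessel_area_density, "vessel_area_density")
  .check_frac(osmotic_reflection, "osmotic_reflection")
  .check_pos(lymph_drainage, "lymph_drainage", strict = FALSE)
  starling_normal <- match.arg(starling_normal)
  structure(list(
    hydraulic_conductivity = hydraulic_conductivity,
    vessel_hydraulic_conductivity = vessel_hydraulic_conductivity,
    vessel_area_density = vessel_area_density,
    vascular_pressure = vascular_pressure,
    plasma_osmotic_pressure = plasma_osmotic_pressure,
    interstitial_osmotic_pressure = interstitial_osmotic_pressure,
    osmotic_reflection = osmotic_reflection,
    lymph_drainage = lymph_drainage,
    starling_normal = starling_normal),
    class = "flow_params")
}

#' Drug and carrier transport parameters
#'
#' Transport and kinetic constants for doxorubicin and its 100 nm
#' temperature-sensitive liposome carrier. Free-drug constants are the
#' standard doxorubicin set; carrier-specific vessel-wall parameters are
#' derived from a hindered-pore closure (see [hindrance_factors()]) unless
#' overridden numerically.
#'
#' @param tsl_diffusivity interstitial diffusivity of the intact carrier,
#'   m2/s. Default from Stokes-Einstein for a 100 nm particle with an
#'   interstitial hindrance factor ~0.25.
#' @param free_drug_diffusivity D_F, m2/s (default 3.4e-6 cm2/s).
#' @param vessel_permeability_free microvessel permeability of free drug,
#'   m/s (default 3e-4 cm/s).
#' @param vessel_permeability_tsl carrier permeability, m/s; `NULL` (default)
#'   derives it from the hindered-pore closure.
#' @param filtration_reflection_free sigma_f of the free drug (small
#'   molecule, default 0).
#' @param filtration_reflection_tsl carrier filtration reflection; `NULL`
#'   derives it from the hindered-pore closure.
#' @param release_rate_at_42 K_EL at/above 42 C, 1/s.
#' @param release_threshold_low,release_threshold_high temperatures (C)
#'   bounding the release ramp: zero release below the low threshold,
#'   plateau `release_rate_at_42` at/above the high threshold.
#' @param release_ramp `"linear"` or `"exponential"` ramp shape between the
#'   thresholds.
#' @param binding_on K_ON, m3/(mol s) (1.5e3 1/(M s)).
#' @param binding_off K_OFF, 1/s.
#' @param internalization K_INT, 1/s.
#' @param accessible_fraction phi_acc, tumor volume fraction accessible to
#'   drug.
#' @param receptor_concentration C_rec, mol/m3 (1e-5 M).
#' @param survival_constant omega, m3/mol, of the exponential dose-response.
#' @param plasma_decay TSL plasma decay time constant k_d, s (mono-exponential
#'   clearance). Default calibrated so the tumor-mean carrier concentration
#'   peaks about 9 h post-injection (methods vignette).
#' @param plasma_decay_free plasma decay time of free doxorubicin for the
#'   conventional-chemotherapy mode, s (minutes-scale distribution
#'   half-life).
#' @param initial_plasma_dose C_p0, mol/m3 (documented range 0.5-1.5).
#' @param carrier_diameter TSL diameter, m.
#' @param vessel_pore_diameter mean tumor vessel-wall pore diameter, m.
#' @param pore_gsd geometric standard deviation of the lognormal pore-radius
#'   distribution of the hindered-pore closure (> 1; 1 = monodisperse).
#' @param pore_reference_permeability permeability scale of an unhindered
#'   transvascular pore pathway for the carrier, m/s; multiplied by the
#'   distribution-averaged hindrance factor to obtain
#'   `vessel_permeability_tsl`. Calibrated against the tumor accumulation
#'   observables (methods vignette).
#' @param normal_pore_diameter vessel-wall pore diameter in normal tissue, m
#'   (< 12 nm, which shuts off carrier extravasation there).
#' @param allow_out_of_range allow `initial_plasma_dose` outside the
#'   documented range.
#' @return object of class `"drug_params"`.
#' @export
drug_params <- function(tsl_diffusivity = 1e-12,
                        free_drug_diffusivity = 3.4e-10,
                        vessel_permeability_free = 3e-6,
                        vessel_permeability_tsl = NULL,
                        filtration_reflection_free = 0,
                        filtration_reflection_tsl = NULL,
                        release_rate_at_42 = 0.05409,
                        release_threshold_low = 39,
                        release_threshold_high = 42,
                        release_ramp = c("linear", "exponential"),
                        binding_on = 1.5,
                        binding_off = 8e-3,
                        internalization = 5e-5,
                        accessible_fraction = 0.3,
                        receptor_concentration = 0.01,
                        survival_constant = 0.6603,
                        plasma_decay = 30 * 3600,
                        plasma_decay_free = 600,
                        initial_plasma_dose = 1.0,
                        carrier_diameter = 100e-9,
                        vessel_pore_diameter = 200e-9,
                        pore_gsd = 2.2,
                        pore_reference_permeability = 1.8e-7,
                        normal_pore_diameter = 12e-9,
                        allow_out_of_range = FALSE) {
  release_ramp <- match.arg(release_ramp)
  .check_pos(tsl_diffusivity, "tsl_diffusivity")
  .check_pos(free_drug_diffusivity, "free_drug_diffusivity")
  .check_pos(vessel_permeability_free, "vessel_permeability_free", strict = FALSE)
  .check_frac(filtration_reflection_free, "filtration_reflection_free")
  .check_pos(release_rate_at_42, "release_rate_at_42")
  if (!(release_threshold_low < release_threshold_high))
    stop("invariant violated: release_threshold_low < release_threshold_high",
         call. = FALSE)
  .check_pos(binding_on, "binding_on", strict = FALSE)
  .check_pos(binding_off, "binding_off", strict = FALSE)
  .check_pos(internalization, "internalization", strict = FALSE)
  .check_frac(accessible_fraction, "accessible_fraction")
  .check_pos(receptor_concentration, "receptor_concentration", strict = FALSE)
  .check_pos(survival_constant, "survival_constant")
  .check_pos(plasma_decay, "plasma_decay")
  .check_pos(plasma_decay_free, "plasma_decay_free")
  .check_pos(initial_plasma_dose, "initial_plasma_dose", strict = FALSE)
  if (!allow_out_of_range && length(initial_plasma_dose) == 1L &&
      (initial_plasma_dose < 0.5 || initial_plasma_dose > 1.5) &&
      initial_plasma_dose != 0)
    stop("invariant violated: `initial_plasma_dose` = ", initial_plasma_dose,
         " mol/m3 is outside the documented range [0.5, 1.5]; set ",
         "`allow_out_of_range = TRUE` to accept it", call. = FALSE)
  .check_pos(carrier_diameter, "carrier_diameter")
  .check_pos(vessel_pore_diameter, "vessel_pore_diameter")
  if (pore_gsd < 1)
    stop("invariant violated: `pore_gsd` must be >= 1", call. = FALSE)
  .check_pos(pore_reference_permeability, "pore_reference_permeability",
             strict = FALSE)
  .check_pos(normal_pore_diameter, "normal_pore_diameter")
  if (!is.null(filtration_reflection_tsl))
    .check_frac(filtration_reflection_tsl, "filtration_reflection_tsl")
  structure(list(
    tsl_diffusivity = tsl_diffusivity,
    free_drug_diffusivity = free_drug_diffusivity,
    vessel_permeability_free = vessel_permeability_free,
    vessel_permeability_tsl = vessel_permeability_tsl,
    filtration_reflection_free = filtration_reflection_free,
    filtration_reflection_tsl = filtration_reflection_tsl,
    release_rate_at_42 = release_rate_at_42,
    release_threshold_low = release_threshold_low,
    release_threshold_high = release_threshold_high,
    release_ramp = release_ramp,
    binding_on = binding_on, binding_off = binding_off,
    internalization = internalization,
    accessible_fraction = accessible_fraction,
    receptor_concentration = receptor_concentration,
    survival_constant = survival_constant,
    plasma_decay = plasma_decay, plasma_decay_free = plasma_decay_free,
    initial_plasma_dose = initial_plasma_dose,
    carrier_diameter = carrier_diameter,
    vessel_pore_diameter = vessel_pore_diameter,
    pore_gsd = pore_gsd,
    pore_reference_permeability = pore_reference_permeability,
    normal_pore_diameter = normal_pore_diameter,
    allow_out_of_range = allow_out_of_range),
    class = "drug_params")
}

#' Full scenario configuration
#'
#' Bundles geometry, all parameter blocks, the treatment schedule and solver
#' controls into one validated object consumed by [run_scenario()].
#'
#' @param geometry list with `injection_radius`, `tumor_radius`,
#'   `outer_radius` in meters (defaults 0.25, 1 and 3 cm).
#' @param thermal list of three [tissue_thermal_params()] named `normal`,
#'   `tumor`, `injection`.
#' @param magnetic a [magnetic_spec()].
#' @param field a [field_spec()].
#' @param arrhenius an [arrhenius_params()].
#' @param flow a [flow_params()].
#' @param drug a [drug_params()].
#' @param schedule list: `mode` one of `"chemo"`, `"mht_only"`,
#'   `"combination"`; `delay` seconds between TSL injection and AMF start;
#'   `amf_duration` seconds of AMF exposure; `horizon` total simulated time
#'   from TSL injection, s; `checkpoint` output cadence, s.
#' @param solver list: nodes per region `n_injection`, `n_tumor`, `n_normal`;
#'   `dt_thermal`, `dt_transport` time steps in s; `cooldown` post-AMF window
#'   simulated thermally, s; `reaction_substeps` RK4 substeps of the local
#'   kinetics per transport step; `seed` optional integer.
#' @return object of class `"scenario_config"`.
#' @export
scenario_config <- function(geometry = list(),
                            thermal = list(),
                            magnetic = magnetic_spec(),
                            field = field_spec(),
                            arrhenius = arrhenius_params(),
                            flow = flow_params(),
                            drug = drug_params(),
                            schedule = list(),
                            solver = list()) {
  geometry <- modifyList(list(injection_radius = 2.5e-3,
                              tumor_radius = 1e-2,
                              outer_radius = 3e-2), geometry)
  if (!(geometry$injection_radius < geometry$tumor_radius &&
        geometry$tumor_radius < geometry$outer_radius))
    stop("invariant violated: injection_radius < tumor_radius < outer_radius",
         call. = FALSE)
  th <- .default_thermal()
  if (length(thermal)) {
    bad <- setdiff(names(thermal), names(th))
    if (length(bad)) stop("unknown thermal region(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    for (nm in names(thermal)) th[[nm]] <- thermal[[nm]]
  }
  stopifnot(inherits(magnetic, "magnetic_spec"),
            inherits(field, "field_spec"),
            inherits(arrhenius, "arrhenius_params"),
            inherits(flow, "flow_params"),
            inherits(drug, "drug_params"))
  schedule <- modifyList(list(mode = "combination",
                              delay = 9 * 3600,
                              amf_duration = field$on_time,
                              horizon = 72 * 3600,
                              checkpoint = 360), schedule)
  schedule$mode <- match.arg(schedule$mode, c("combination", "chemo", "mht_only"))
  if (schedule$delay < 0) stop("invariant violated: `delay` must be >= 0",
                               call. = FALSE)
  solver <- modifyList(list(n_injection = 20, n_tumor = 60, n_normal = 60,
                            dt_thermal = 3.6, dt_transport = 3.6,
                            cooldown = 5400, reaction_substeps = 4,
                            seed = NULL), solver)
  if (solver$n_tumor < 50)
    stop("invariant violated: at least 50 nodes across the tumor are required",
         call. = FALSE)
  structure(list(geometry = geometry, thermal = th, magnetic = magnetic,
                 field = field, arrhenius = arrhenius, flow = flow,
                 drug = drug, schedule = schedule, solver = solver),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  g <- x$geometry
  cat("<scenario_config>\n")
  cat(sprintf("  mode: %s | geometry r = %.2f / %.1f / %.1f cm\n",
              x$schedule$mode, 100 * g$injection_radius,
              100 * g$tumor_radius, 100 * g$outer_radius))
  cat(sprintf("  AMF: %.0f kA/m @ %.0f kHz, start %.1f h, duration %.0f min\n",
              x$field$amplitude / 1e3, x$field$frequency / 1e3,
              x$schedule$delay / 3600, x$schedule$amf_duration / 60))
  cat(sprintf("  dose Cp0 = %.2f mol/m3 | horizon %.0f h | dt = %.4g h\n",
              x$drug$initial_plasma_dose, x$schedule$horizon / 3600,
              x$solver$dt_transport / 3600))
  invisible(x)
}
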