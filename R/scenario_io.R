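# YAML scenario I/O. Canonical keys are the constructor argument names in SI
# units; a handful of convenience keys with explicit unit suffixes are accepted
# on input and converted at this single boundary.

# convenience-key -> c(canonical, from_unit, to_unit)
.convenience_keys <- list(
  geometry = list(
    injection_radius_cm = c("injection_radius", "cm", "m"),
    tumor_radius_cm     = c("tumor_radius", "cm", "m"),
    outer_radius_cm     = c("outer_radius", "cm", "m")),
  field = list(
    amplitude_ka_per_m  = c("amplitude", "kA_per_m", "A_per_m")),
  flow = list(
    hydraulic_conductivity_cm2_per_mmhg_s =
      c("hydraulic_conductivity", "cm2_per_mmHg_s", "m2_per_Pa_s"),
    vessel_hydraulic_conductivity_cm_per_mmhg_s =
      c("vessel_hydraulic_conductivity", "cm_per_mmHg_s", "m_per_Pa_s"),
    vessel_area_density_per_cm = c("vessel_area_density", "per_cm", "per_m"),
    vascular_pressure_mmhg = c("vascular_pressure", "mmHg", "Pa"),
    plasma_osmotic_pressure_mmhg = c("plasma_osmotic_pressure", "mmHg", "Pa"),
    interstitial_osmotic_pressure_mmhg =
      c("interstitial_osmotic_pressure", "mmHg", "Pa")),
  drug = list(
    free_drug_diffusivity_cm2_per_s =
      c("free_drug_diffusivity", "cm2_per_s", "m2_per_s"),
    vessel_permeability_free_cm_per_s =
      c("vessel_permeability_free", "cm_per_s", "m_per_s"),
    receptor_concentration_molar = c("receptor_concentration", "M", "mol_m3"),
    plasma_decay_h = c("plasma_decay", "h", "s"),
    carrier_diameter_nm = c("carrier_diameter", "nm", "m"),
    vessel_pore_diameter_nm = c("vessel_pore_diameter", "nm", "m")),
  schedule = list(
    delay_h = c("delay", "h", "s"),
    amf_duration_h = c("amf_duration", "h", "s"),
    horizon_h = c("horizon", "h", "s"),
    checkpoint_h = c("checkpoint", "h", "s")),
  solver = list(
    dt_thermal_h = c("dt_thermal", "h", "s"),
    dt_transport_h = c("dt_transport", "h", "s"))
)

.resolve_block <- function(block, values, allowed) {
  conv <- .convenience_keys[[block]]
  out <- list()
  for (key in names(values)) {
    if (!is.null(conv[[key]])) {
      spec <- conv[[key]]
      out[[spec[[1]]]] <- convert_units(values[[key]], spec[[2]], spec[[3]])
    } else if (key %in% allowed) {
      out[[key]] <- values[[key]]
    } else {
      stop("unknown key `", block, ".", key, "` in scenario document",
           call. = FALSE)
    }
  }
  out
}

.block_args <- list(
  geometry = c("injection_radius", "tumor_radius", "outer_radius"),
  magnetic = names(formals(magnetic_spec)),
  field = names(formals(field_spec)),
  arrhenius = names(formals(arrhenius_params)),
  flow = names(formals(flow_params)),
  drug = names(formals(drug_params)),
  schedule = c("mode", "delay", "amf_duration", "horizon", "checkpoint"),
  solver = c("n_injection", "n_tumor", "n_normal", "dt_thermal",
             "dt_transport", "cooldown", "reaction_substeps", "seed")
)

#' Load a scenario configuration from a YAML document
#'
#' Reads a structured scenario document (blocks `geometry`, `thermal`,
#' `magnetic`, `field`, `arrhenius`, `flow`, `drug`, `schedule`, `solver`),
#' applies it on top of the package defaults, converts the few
#' unit-suffixed convenience keys to SI, and validates every invariant.
#' An empty document yields the all-defaults configuration.
#'
#' @param source a file path or a literal YAML string.
#' @return a validated [scenario_config()].
#' @export
load_scenario <- function(source) {
  doc <- if (length(source) == 1L && !grepl("\n", source) && file.exists(source))
    yaml::read_yaml(source) else yaml::yaml.load(source)
  if (is.null(doc)) doc <- list()
  known_blocks <- c("geometry", "thermal", names(.block_args)[-1])
  bad <- setdiff(names(doc), known_blocks)
  if (length(bad))
    stop("unknown block(s) in scenario document: ",
         paste(bad, collapse = ", "), call. = FALSE)

  args <- list()
  for (blk in c("geometry", "schedule", "solver")) {
    if (!is.null(doc[[blk]]))
      args[[blk]] <- .resolve_block(blk, doc[[blk]], .block_args[[blk]])
  }
  for (blk in c("magnetic", "field", "arrhenius", "flow", "drug")) {
    if (!is.null(doc[[blk]])) {
      ctor <- switch(blk, magnetic = magnetic_spec, field = field_spec,
                     arrhenius = arrhenius_params, flow = flow_params,
                     drug = drug_params)
      vals <- .resolve_block(blk, doc[[blk]], .block_args[[blk]])
      args[[blk]] <- do.call(ctor, vals)
    }
  }
  if (!is.null(doc$thermal)) {
    regions <- list()
    defaults <- .default_thermal()
    bad <- setdiff(names(doc$thermal), names(defaults))
    if (length(bad))
      stop("unknown key `thermal.", bad[[1]], "` in scenario document",
           call. = FALSE)
    allowed <- names(formals(tissue_thermal_params))
    for (reg in names(doc$thermal)) {
      vals <- .resolve_block(paste0("thermal.", reg), doc$thermal[[reg]],
                             allowed)
      regions[[reg]] <- do.call(tissue_thermal_params,
                                modifyList(unclass(defaults[[reg]]), vals))
    }
    args$thermal <- regions
  }
  do.call(scenario_config, args)
}

#' Serialize a resolved scenario configuration to YAML
#'
#' Emits the fully resolved, SI-unit configuration using canonical keys, so
#' that `load_scenario(scenario_to_yaml(cfg))` reproduces `cfg` exactly.
#'
#' @param config a [scenario_config()].
#' @param file optional path; if given the YAML is written there.
#' @return the YAML text, invisibly if `file` is given.
#' @export
scenario_to_yaml <- function(config, file = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  strip <- function(x) lapply(unclass(x), function(v) v)
  doc <- list(
    geometry = config$geometry,
    thermal = lapply(config$thermal, strip),
    magnetic = strip(config$magnetic),
    field = strip(config$field),
    arrhenius = strip(config$arrhenius),
    flow = strip(config$flow),
    drug = strip(config$drug),
    schedule = config$schedule,
    solver = config$solver
  )
  # drop non-constructor fields and NULLs so the document reloads cleanly
  doc$field$vacuum_permeability <- NULL
  doc <- lapply(doc, function(b) b[!vapply(b, is.null, logical(1))])
  txt <- yaml::as.yaml(doc, precision = 15)
  if (!is.null(file)) { writeLines(txt, file); return(invisible(txt)) }
  txt
}
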