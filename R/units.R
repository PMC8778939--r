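#' Unit conversion for simulator I/O
#'
#' The solver works in SI units throughout; the tumor-physiology literature
#' mixes mmHg, cm, hours and molar concentrations, so conversions happen in a
#' single place at the configuration boundary.
#'
#' Supported pairs (both directions): mmHg/Pa, cm/m, h/s, min/s, M/mol_m3,
#' cm2_per_mmHg_s/m2_per_Pa_s (interstitial hydraulic conductivity),
#' cm_per_mmHg_s/m_per_Pa_s (vessel-wall hydraulic conductivity),
#' cm_per_s/m_per_s, cm2_per_s/m2_per_s, per_cm/per_m, kA_per_m/A_per_m,
#' nm/m, C/K.
#'
#' @param value numeric vector of quantities expressed in `from`.
#' @param from,to unit names (see Details).
#' @return numeric vector in `to` units.
#' @examples
#' convert_units(15.6, "mmHg", "Pa")   # vascular pressure of Table-type inputs
#' convert_units(1, "M", "mol_m3")
#' @export
convert_units <- function(value, from, to) {
  stopifnot(is.numeric(value), length(from) == 1L, length(to) == 1L)
  if (from == to) return(value)
  key <- paste(from, to, sep = "->")
  # affine conversions (temperature)
  if (key == "C->K") return(value + 273.15)
  if (key == "K->C") return(value - 273.15)
  f <- .unit_factors[[key]]
  if (is.null(f)) {
    inv <- .unit_factors[[paste(to, from, sep = "->")]]
    if (is.null(inv)) {
      stop("unsupported unit conversion: ", from, " -> ", to, call. = FALSE)
    }
    f <- 1 / inv
  }
  value * f
}

# 1 mmHg in Pa; the conventional 133.322 Pa definition
.MMHG <- 133.322

.unit_factors <- local({
  base <- list(
    "mmHg->Pa"   = .MMHG,
    "cm->m"      = 1e-2,
    "nm->m"      = 1e-9,
    "h->s"       = 3600,
    "min->s"     = 60,
    "M->mol_m3"  = 1000,
    "cm_per_s->m_per_s"   = 1e-2,
    "cm2_per_s->m2_per_s" = 1e-4,
    "per_cm->per_m"       = 1e2,
    "kA_per_m->A_per_m"   = 1e3,
    "cm2_per_mmHg_s->m2_per_Pa_s" = 1e-4 / .MMHG,
    "cm_per_mmHg_s->m_per_Pa_s"   = 1e-2 / .MMHG
  )
  base
})
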