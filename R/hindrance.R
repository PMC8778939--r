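# Hindered transvascular transport of the liposomal carrier.
#
# The carrier's vessel-wall permeability and filtration reflection are not
# tabulated anywhere; they are closed with classical pore-hindrance theory
# applied to a polydisperse population of cylindrical wall pores. Tumor
# vessel-wall openings are strongly heterogeneous, so a lognormal pore-radius
# distribution is used; diffusive transport is weighted by pore cross-section
# (r^2) and convective transport by Poiseuille conductance (r^4). A single
# calibrated permeability scale (the unhindered-pathway permeability) maps
# the dimensionless hindrance factor to m/s.

#' Renkin diffusive hindrance factor
#'
#' `F(lambda) = (1-lambda)^2 (1 - 2.104 lambda + 2.09 lambda^3 -
#' 0.95 lambda^5)` for the ratio `lambda` of solute to pore radius, clamped
#' to zero for `lambda >= 1` (steric exclusion).
#'
#' @param lambda solute radius / pore radius (vectorized).
#' @return dimensionless factor in `[0, 1]`.
#' @export
renkin_diffusive <- function(lambda) {
  f <- (1 - lambda)^2 *
    (1 - 2.104 * lambda + 2.09 * lambda^3 - 0.95 * lambda^5)
  ifelse(lambda >= 1 | f < 0, 0, f)
}

#' Convective hindrance and single-pore reflection coefficient
#'
#' Anderson-Quinn-type convective hindrance
#' `W(lambda) = Phi (2 - Phi) (1 - lambda^2 / 3)` with partition coefficient
#' `Phi = (1 - lambda)^2`; the osmotic/filtration reflection of a single pore
#' is `sigma = 1 - W`.
#'
#' @inheritParams renkin_diffusive
#' @return list with `W` and `sigma`.
#' @export
convective_hindrance <- function(lambda) {
  phi <- pmax(1 - lambda, 0)^2
  W <- phi * (2 - phi) * (1 - pmin(lambda, 1)^2 / 3)
  list(W = W, sigma = 1 - W)
}

#' Distribution-averaged hindrance of a carrier in a polydisperse pore wall
#'
#' Averages the single-pore hindrance factors over a lognormal pore-radius
#' distribution with median radius `pore_diameter / 2` and geometric standard
#' deviation `gsd`. The diffusive factor is pore-area (r^2) weighted and the
#' reflection coefficient is Poiseuille-flow (r^4) weighted.
#'
#' @param carrier_diameter carrier diameter, m.
#' @param pore_diameter median pore diameter, m.
#' @param gsd geometric standard deviation of the pore radius (1 =
#'   monodisperse).
#' @param nq quadrature points.
#' @return list with `diffusive` (mean Renkin factor, in `[0, 1]`) and `sigma_f`
#'   (flow-weighted filtration reflection).
#' @export
hindrance_factors <- function(carrier_diameter, pore_diameter, gsd = 1,
                              nq = 128) {
  stopifnot(carrier_diameter > 0, pore_diameter > 0, gsd >= 1)
  a <- carrier_diameter / 2
  if (gsd == 1) {
    lam <- a / (pore_diameter / 2)
    return(list(diffusive = renkin_diffusive(lam),
                sigma_f = convective_hindrance(lam)$sigma))
  }
  # midpoint quadrature in the Gaussian quantile domain
  z <- qnorm((seq_len(nq) - 0.5) / nq)
  rp <- (pore_diameter / 2) * exp(log(gsd) * z)
  lam <- a / rp
  w2 <- rp^2; w4 <- rp^4
  diffusive <- sum(renkin_diffusive(lam) * w2) / sum(w2)
  sigma_f <- 1 - sum(convective_hindrance(lam)$W * w4) / sum(w4)
  list(diffusive = diffusive, sigma_f = sigma_f)
}

#' Resolved carrier vessel-wall parameters
#'
#' Applies the hindered-pore closure to a [drug_params()] object, honoring
#' explicit numeric overrides. In normal tissue the vessel-wall pores
#' (< 12 nm) exclude the 100 nm carrier entirely, so carrier extravasation is
#' confined to the tumor.
#'
#' @param drug a [drug_params()].
#' @return list with `P_tsl` (m/s), `sigma_f_tsl`, `P_tsl_normal`.
#' @export
tsl_vessel_params <- function(drug) {
  hf <- hindrance_factors(drug$carrier_diameter, drug$vessel_pore_diameter,
                          drug$pore_gsd)
  hf_n <- hindrance_factors(drug$carrier_diameter, drug$normal_pore_diameter,
                            drug$pore_gsd)
  P <- drug$vessel_permeability_tsl
  if (is.null(P)) P <- drug$pore_reference_permeability * hf$diffusive
  s <- drug$filtration_reflection_tsl
  if (is.null(s)) s <- hf$sigma_f
  list(P_tsl = P, sigma_f_tsl = s,
       P_tsl_normal = drug$pore_reference_permeability * hf_n$diffusive)
}
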