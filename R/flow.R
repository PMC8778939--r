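# Steady Darcy interstitial fluid mechanics with a Starling transvascular
# source. The flow field is solved once per scenario and frozen for the
# transport problem (temperature does not feed back on flow).

#' Solve the steady interstitial fluid pressure and velocity
#'
#' Finite-volume solve of `-div(kappa grad p) = phi_B - phi_L` with the
#' Starling source `phi_B = L_p S/V (P_b - p - sigma_s (pi_B - pi_i))` active
#' in the tumor (including the injection site), no functional lymphatics
#' inside the tumor, zero pressure at the outer boundary and zero flux at the
#' center. Normal-tissue handling (`flow_params(starling_normal = ...)`):
#' `"sink"` (default) places functional lymphatics in normal tissue that
#' drain at rate `L_p S/V p` (filtration there is otherwise balanced), which
#' absorbs the tumor filtrate within a thin peritumoral layer and reproduces
#' the steep experimental IFP drop at the tumor edge; `"balanced"` removes
#' both source and sink (pressure then relaxes to the outer boundary by
#' conduction alone); `"full"` extends the Starling source to normal tissue.
#'
#' @param grid a [radial_grid()].
#' @param flow a [flow_params()].
#' @return object of class `"flow_solution"`: `p` (Pa), `p_mmHg`, `u_face`
#'   (radial interstitial fluid velocity at interior faces, m/s), `u_node`
#'   (node-interpolated velocity), `phiB` (fluid source, 1/s), `phiL`
#'   (lymphatic drainage, 1/s), `pe` (effective filtration pressure, Pa),
#'   `mass_balance` (relative residual of net source vs boundary outflow),
#'   `grid`.
#' @export
solve_ifp <- function(grid, flow = flow_params()) {
  stopifnot(inherits(grid, "radial_grid"), inherits(flow, "flow_params"))
  n <- grid$n
  kappa <- flow$hydraulic_conductivity
  if (kappa <= 0) stop("hydraulic conductivity must be positive", call. = FALSE)
  pe <- flow$vascular_pressure - flow$osmotic_reflection *
    (flow$plasma_osmotic_pressure - flow$interstitial_osmotic_pressure)
  lpsv <- flow$vessel_hydraulic_conductivity * flow$vessel_area_density
  src_on <- grid$region %in% c("injection", "tumor")
  if (flow$starling_normal == "full") src_on <- rep(TRUE, n)
  sink_on <- grid$region == "normal" & flow$starling_normal == "sink"
  dr <- diff(grid$r)
  G <- grid$face_area * kappa / dr
  diagv <- numeric(n); lower <- numeric(n); upper <- numeric(n); rhs <- numeric(n)
  sV <- ifelse(src_on | sink_on, lpsv, 0) * grid$volume
  diagv <- sV
  rhs <- ifelse(src_on, lpsv * pe, 0) * grid$volume
  lower[-1] <- -G; upper[-n] <- -G
  diagv[-1] <- diagv[-1] + G
  diagv[-n] <- diagv[-n] + G
  lower[n] <- 0; upper[n] <- 0; diagv[n] <- 1; rhs[n] <- 0  # outer Dirichlet
  if (all(sV[-n] == 0)) {
    p <- numeric(n)  # no source anywhere: singular Neumann core, p = 0
  } else {
    p <- .cpp_thomas(lower, diagv, upper, rhs)
  }
  u_face <- -kappa * diff(p) / dr
  u_node <- c(0, (u_face[-(n - 1)] + u_face[-1]) / 2, u_face[n - 1])
  phiB <- ifelse(src_on, lpsv * (pe - p), 0)
  phiL <- ifelse(sink_on, lpsv * p, 0)
  out <- sum(((phiB - phiL) * grid$volume)[-n])
  bnd <- grid$face_area[n - 1] * u_face[n - 1]
  src_tot <- sum((phiB * grid$volume)[-n])
  mb <- if (src_tot == 0) 0 else abs(out - bnd) / abs(src_tot)
  structure(list(p = p, p_mmHg = convert_units(p, "Pa", "mmHg"),
                 u_face = u_face, u_node = u_node, phiB = phiB, phiL = phiL,
                 pe = pe,
                 mass_balance = mb, grid = grid, flow = flow),
            class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf("<flow_solution> central IFP %.2f mmHg (pe = %.2f mmHg); peak IFV %.3g um/s\n",
              x$p_mmHg[1], convert_units(x$pe, "Pa", "mmHg"),
              1e6 * max(abs(x$u_face))))
  invisible(x)
}

#' Closed-form interstitial pressure in a homogeneous source sphere
#'
#' Analytic solution of the Darcy-Starling balance for a single homogeneous
#' sphere of radius `R` with uniform Starling source and `p(R) = 0`:
#' `p(r) = pe (1 - (R/r) sinh(alpha r / R) / sinh(alpha))` with
#' `alpha = R sqrt(L_p S/V / kappa)`. Serves as the independent oracle for
#' [solve_ifp()].
#'
#' @param flow a [flow_params()].
#' @param R sphere radius, m.
#' @param r radii at which to evaluate, m.
#' @return pressures, Pa.
#' @export
analytic_ifp_sphere <- function(flow, R, r) {
  pe <- flow$vascular_pressure - flow$osmotic_reflection *
    (flow$plasma_osmotic_pressure - flow$interstitial_osmotic_pressure)
  alpha <- R * sqrt(flow$vessel_hydraulic_conductivity *
                      flow$vessel_area_density / flow$hydraulic_conductivity)
  if (alpha == 0) return(rep(0, length(r)))
  x <- alpha * r / R
  ratio <- ifelse(r == 0, alpha / sinh(alpha), (R / r) * sinh(x) / sinh(alpha))
  pe * (1 - ratio)
}
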