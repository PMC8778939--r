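#' Neel/Brown relaxation times of a superparamagnetic suspension
#'
#' Brownian rotation time `tau_B = 3 delta V_H / (k_B T_s)` and Neel reversal
#' time as a function of the anisotropy ratio
#' `Gamma = K_eff V_H / (k_B T_s)`; the effective time is their harmonic
#' combination `tau_eff = tau_B tau_N / (tau_B + tau_N)`.
#'
#' Two Neel forms are available: the standard linear-response-theory
#' expression `tau_N = (sqrt(pi)/2) tau_0 exp(Gamma) / sqrt(Gamma)`
#' (`"rosensweig"`, default) and a literal variant
#' `tau_N = pi tau_0 exp(Gamma) / (2 Gamma)` kept for sensitivity studies.
#'
#' @param spec a [magnetic_spec()].
#' @param Ts suspension absolute temperature, K.
#' @param neel_form `"rosensweig"` or `"literal"`.
#' @return object of class `"relaxation_times"`: list with `brown`, `neel`,
#'   `effective` (s) and `anisotropy_ratio`.
#' @export
relaxation_times <- function(spec, Ts = 310.15,
                             neel_form = c("rosensweig", "literal")) {
  stopifnot(inherits(spec, "magnetic_spec"), Ts > 0)
  neel_form <- match.arg(neel_form)
  vh <- hydrodynamic_volume(spec)
  if (vh <= 0) stop("non-physical spec: zero hydrodynamic volume", call. = FALSE)
  kT <- .kB * Ts
  tauB <- 3 * spec$suspension_viscosity * vh / kT
  Gamma <- spec$anisotropy_constant * vh / kT
  if (!is.finite(Gamma)) stop("non-finite anisotropy ratio", call. = FALSE)
  tauN <- switch(neel_form,
    rosensweig = sqrt(pi) / 2 * spec$attempt_time * exp(Gamma) / sqrt(Gamma),
    literal    = pi * spec$attempt_time * exp(Gamma) / (2 * Gamma))
  structure(list(brown = tauB, neel = tauN,
                 effective = tauB * tauN / (tauB + tauN),
                 anisotropy_ratio = Gamma),
            class = "relaxation_times")
}

#' @export
print.relaxation_times <- function(x, ...) {
  cat(sprintf("<relaxation_times> tau_B = %.3g s, tau_N = %.3g s, tau_eff = %.3g s (Gamma = %.3g)\n",
              x$brown, x$neel, x$effective, x$anisotropy_ratio))
  invisible(x)
}

#' Equilibrium (chord) susceptibility of the suspension
#'
#' Field-dependent chord susceptibility
#' `chi_0 = chi_i (3/xi) (coth(xi) - 1/xi)` with Langevin argument
#' `xi = mu_0 M_d H_m V_M / (k_B T_s)` and initial susceptibility
#' `chi_i = mu_0 M_d^2 V_M / (3 k_B T_s)` defined per unit particle volume
#' (the volume fraction enters the dissipated power exactly once, explicitly).
#' As `H_m -> 0` the chord factor tends to 1 and `chi_0 -> chi_i`.
#'
#' @param spec a [magnetic_spec()].
#' @param field a [field_spec()] (only the amplitude is used).
#' @param Ts suspension temperature, K.
#' @return scalar `chi_0` (dimensionless).
#' @export
equilibrium_susceptibility <- function(spec, field, Ts = 310.15) {
  stopifnot(inherits(spec, "magnetic_spec"), inherits(field, "field_spec"),
            Ts > 0)
  vm <- magnetic_volume(spec)
  kT <- .kB * Ts
  chi_i <- .MU0 * spec$domain_magnetization^2 * vm / (3 * kT)
  xi <- .MU0 * spec$domain_magnetization * field$amplitude * vm / kT
  chi_i * .langevin_chord(xi)
}

# (3/xi) * L(xi) with L the Langevin function; -> 1 as xi -> 0
.langevin_chord <- function(xi) {
  ifelse(abs(xi) < 1e-4,
         1 - xi^2 / 15,
         3 / xi * (1 / tanh(xi) - 1 / xi))
}

#' Volumetric power deposited by MNPs under an alternating field
#'
#' Linear-response (relaxation-loss) dissipation
#' `Q_MNP = phi mu_0 chi_0 H_m^2 f * 2 pi f tau_eff / (1 + (2 pi f tau_eff)^2)`,
#' in W/m3 of ferrofluid. The frequency bracket is maximal when
#' `2 pi f tau_eff = 1`. The optional `rosensweig_pi` switch inserts the
#' textbook extra factor pi for sensitivity studies (default off).
#'
#' @inheritParams equilibrium_susceptibility
#' @param rosensweig_pi logical; multiply by pi.
#' @param neel_form passed to [relaxation_times()].
#' @return power density, W/m3.
#' @export
volumetric_power <- function(spec, field, Ts = 310.15,
                             rosensweig_pi = FALSE,
                             neel_form = "rosensweig") {
  tau <- relaxation_times(spec, Ts, neel_form = neel_form)$effective
  chi0 <- equilibrium_susceptibility(spec, field, Ts)
  wt <- 2 * pi * field$frequency * tau
  q <- spec$volume_fraction * .MU0 * chi0 * field$amplitude^2 *
    field$frequency * wt / (1 + wt^2)
  if (rosensweig_pi) q <- pi * q
  q
}
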