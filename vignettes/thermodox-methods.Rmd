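---
title: "Modeling magnetically triggered liposomal chemotherapy: methods and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling magnetically triggered liposomal chemotherapy: methods and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the science implemented in `thermodox`, the
numerical scheme, how the constants that are not fixed by published property
tables were chosen, and what the package's validation does and does not
establish. It states no result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Geometry and what the scenarios emulate

The model is a nested spherical idealization of a preclinical protocol:
temperature-sensitive liposomes loaded with doxorubicin (TSL-Dox) are given
as an intravenous bolus; magnetic nanoparticles (MNPs) are injected
intratumorally, forming a ferrofluid-saturated sphere of radius 0.25 cm at
the center of a 1 cm tumor embedded in normal tissue out to 3 cm; an
alternating magnetic field (AMF, 400 kHz, 11-13 kA/m) then heats the core
for 60 min. The stated geometry is fully spherically symmetric, so the
problem is reduced to one radial dimension; everything the 2-D axisymmetric
finite-element treatments of this protocol resolve is, for this geometry,
a function of radius alone. What the reduction does *not* emulate: discrete
vasculature, intratumoral heterogeneity (necrotic core, perfusion hot
spots), irregular tumor shape, and MNP redistribution after injection.
Passing tests therefore demonstrate internal correctness of the coupled
solvers and consistency with the printed observables of the idealized
protocol — not predictive accuracy for any real tumor.

Three material regions follow the three-column property table convention of
MNP hyperthermia models (normal tissue / tumor / magnetite): the injection
region carries the magnetite-dominated values (rho = 5180 kg/m3, C = 670
J/kg C, k = 528 W/m C). The high conductivity makes the injection site
nearly isothermal, which is also what produces the flat core of the
published temperature profiles.

## Magnetic heating

Power deposition uses linear-response (relaxation-loss) theory for
single-domain superparamagnetic particles (core diameter capped at 20 nm):

* the dissipated power is implemented exactly as
  `Q = phi mu0 chi0 Hm^2 f * wt/(1+wt^2)` with `wt = 2 pi f tau_eff`; a
  `rosensweig_pi` switch adds the textbook extra factor pi for sensitivity
  studies (default off, for fidelity to the source formulation);
* the Neel time is the standard `(sqrt(pi)/2) tau0 e^Gamma / sqrt(Gamma)`;
  the typographically ambiguous variant `pi tau0 e^Gamma / (2 Gamma)` is
  available as `neel_form = "literal"`;
* the equilibrium susceptibility is the Langevin *chord* susceptibility
  `chi_i (3/xi)(coth xi - 1/xi)`, with `chi_i` defined per unit particle
  volume so that the explicit volume fraction in `Q` is applied exactly
  once. Relaxation times are evaluated at body temperature (310.15 K); their
  temperature dependence over the 37-45 C range changes `Q` by under 2% and
  is neglected.

Magnetite defaults: domain magnetization 446 kA/m, attempt time 1e-9 s,
suspension viscosity 1e-3 Pa s. The effective anisotropy constant is the
designated calibration knob (below).

## Bioheat and thermal kill

The Pennes equation is integrated implicitly (backward Euler, default time
step 0.001 h) on a node-centered finite-volume grid with zero flux at the
center and a 37 C Dirichlet condition at the outer boundary; the initial
state is uniformly 37 C. Perfusion and thermal properties are
temperature-independent — hyperthermia-induced changes in blood flow and
vascular permeability are deliberately excluded, so reported efficacies are
conservative in that respect. Thermal damage accumulates per node by
trapezoidal integration of the Arrhenius rate (A = 1.98e106 1/s, dE =
6.67e5 J/mol); accumulation continues through a 1.5 h post-AMF cool-down.

Blood properties (rho_b C_b = 3.6e6 J/m3 K), metabolic heat (420 W/m3) and
perfusion are not part of the printed tables. Perfusion is the thermal
calibration's second knob; the calibrated value (5e-5 1/s in all regions)
sits at the low end of solid-tumor estimates and makes the temperature
field conduction-dominated. A consequence worth knowing: the center
temperature reaches 95% of its steady rise in about 13 min (close to the
~15 min plateau the source protocol describes) but needs ~28 min for the
last percent.

## Interstitial flow

Steady Darcy flow with a Starling source is solved once and frozen (no
thermal feedback, consistent with the bioheat assumptions). Inside the
tumor there is no functional lymphatic drainage; the effective filtration
pressure is `pe = 15.6 - 0.82 (20 - 15) = 11.5 mmHg` and, because the
source/conduction length scale `sqrt(kappa / (Lp S/V))` is ~0.3 mm, the
interstitial pressure plateaus at `pe` through almost the whole tumor and
filtration survives only in a thin rim.

Normal tissue required a design decision. A source-free normal shell
("balanced" Starling) does *not* produce the steep pressure drop at the
tumor edge seen in classic needle-measurement profiles: the filtrate then
has to escape by conduction to the far boundary and the peritumoral
pressure stays near 11 mmHg (we verified this directly). The default is
therefore a peritumoral lymphatic sink, `phi_L = Lp S/V p`, which absorbs
the filtrate within a thin layer and restores the experimental shape;
`starling_normal = "balanced"` and `"full"` remain available.

## Drug transport

Four compartments on the same grid: encapsulated carrier CL and free drug
CF are mobile (diffusion plus interstitial convection); bound CB and
internalized CI are cell-associated and immobile. Plasma concentration
decays mono-exponentially from the bolus. Transvascular exchange uses the
Patlak form with the transvascular Peclet number; the convective and
diffusive pathways and the filtration reflection differ between the small
free drug (printed values: P = 3e-4 cm/s, sigma_f = 0) and the 100 nm
carrier, whose wall transport is closed with hindered-pore theory:
Renkin diffusive hindrance and an Anderson-Quinn-type convective hindrance,
averaged over a lognormal pore-radius distribution (pore-area weighting for
diffusion, Poiseuille r^4 weighting for convection). The same closure
yields zero carrier extravasation in normal tissue (pores < 12 nm), the
documented selectivity advantage of liposomal carriers. Release from the
carrier is zero below 39 C, the printed constant 0.05409 1/s at and above
42 C, and a linear ramp in between (an exponential ramp is available); the
sub-39 C leak is fixed at zero. In the tumor the released free drug has no
transvascular term (it is produced and consumed interstitially); in normal
tissue free drug is cleared by the microvessels in both treatment modes,
and binding/internalization act on tumor cells only.

Drug-induced kill is `FKC = 1 - exp(-omega CI)` per node. The reported
scalar is the volume average of the *local* FKC, not the FKC of the average
concentration (Jensen's inequality makes the latter systematically larger
for heterogeneous fields; the package reports `mean_ci` alongside so the
difference is visible). Combined efficacy multiplies the independent
survival fractions, `S = DS exp(-omega CI)`; the terminal decomposition
credits overlap to heat first (heat share `1 - <DS>`, drug share
`<DS> - <S>`, survivors `<S>`), matching the way per-mechanism shares are
usually reported for this protocol.

## Numerics

* Node-centered finite volumes; region interfaces coincide with grid nodes
  and interface control volumes are split geometrically, so region volumes
  (and the integrated MNP source power) are exact at any resolution.
  Volumetric coefficients are region-volume weighted on interface cells;
  face conductivities/diffusivities use harmonic means. The steady thermal
  field converges at second order under grid halving.
* Transport uses operator splitting per step: local kinetics and
  transvascular exchange first (RK4 with 4 substeps, plasma and release
  forcing evaluated continuously in time), then implicit upwind
  convection-diffusion for the mobile species. In the well-mixed reduction
  the scheme matches an independent stiff ODE integration to 1e-6 relative.
* Defaults: 141 nodes (20/60/60 intervals per region), 0.001 h steps for
  both heat and transport, 72 h horizon. A combination run takes a few
  seconds. These sizes were chosen as the point where halving the step or
  doubling the grid changes the reported efficacies in the third decimal.
* Audits run on every scenario: drug mass balance (influx minus boundary
  outflux vs stored mass; a drift above 0.5% is a hard error), steady
  thermal energy balance, and fluid mass balance. Negative concentrations
  beyond 1e-9 abort the step. Fixed-step runs are bit-reproducible.
* Degenerate inputs are defined: zero dose propagates exact zeros; zero
  vessel conductivity gives zero flow; `Hm = 0` or `phi = 0` gives zero
  power; an AMF that never fires leaves the free-drug compartment at zero.

## Calibration of unprinted constants

Several constants the model needs are not in the published property tables.
They were calibrated once, against printed observables, by
`scripts/calibrate.R`, and frozen as defaults:

* **Keff = 37025 J/m3** (with perfusion 5e-5 1/s): joint equal-error fit of
  the 60-min, 11 kA/m probe pair to the printed 42.2 C (injection center) /
  38.5 C (tumor border). A single-amplitude source cannot hit both exactly:
  with a 0.25 cm source, an isothermal injection site and a 3 cm Dirichlet
  shell, the border/center rise ratio is capped near 0.19 by geometry,
  below the ~0.29 the printed pair implies, so the calibration lands at
  42.62/38.08 C — both residuals 0.43 C. The calibrated Keff is inside the
  range reported for magnetite nanoparticles (1e4-4e4 J/m3).
* **kd = 30 h, pore reference permeability 1.8e-7 m/s, pore gsd = 2.2**:
  fitted to the combination scenario's uptake/efficacy observables — peak
  tumor-mean internalized concentration ~1.2 mol/m3 (treated as a band
  constraint, since it is the loosest-reported observable), with the
  terminal combined kill (~0.50), the 48-h-delay efficacy (~0.21), the
  1.5x-dose efficacy (~0.63) and the 100 vs 200 nm pore efficacy contrast
  (~0.42 vs ~0.52) fitted by least squares over a candidate grid.
  With mono-exponential plasma decay and reversible transvascular exchange
  these targets are incompatible with a 9 h peak of the tumor carrier
  concentration: a late interstitial peak requires slow exchange, which
  caps total uptake far below the printed internalized levels. The
  uptake/efficacy observables won; the simulated tumor-mean carrier curve
  consequently peaks within the first hours, tracking plasma, rather than
  at 9 h. Reproducing both would need a multi-compartment systemic model
  (out of scope). For the same reason the model predicts no *penalty* for
  applying the AMF immediately after injection — efficacy decreases
  monotonically with delay — whereas an accumulation-limited system shows
  an interior optimum.

One related discrepancy is deliberate and left visible: the heat-only kill
at 13 kA/m. With the printed Arrhenius constants and the center temperature
calibrated to the printed 42.2 C at 11 kA/m, meaningful Arrhenius kill at
13 kA/m is confined to roughly r < 0.35 cm and the tumor-volume average of
`1 - DS` is ~5%. The ~15% figure quoted for heat alone coincides with the
volume fraction that *reaches hyperthermic temperatures* (>= 40 C), which
is a thermal-coverage measure, not an Arrhenius volume average; the two
cannot agree under the stated constants. The acceptance script reports the
Arrhenius average as defined.

## Limitations

Beyond the 1-D reduction: monodisperse particles (no size distribution or
hysteresis losses); no MNP migration after injection; mono-exponential
plasma pharmacokinetics; no drug resistance, repair kinetics, cell-cycle
dependence or regrowth; no temperature dependence of perfusion or
permeability; tumor-uniform transport properties. The hindered-pore closure
replaces unpublished carrier transport parameters and its absolute scale is
calibrated, so carrier-side predictions inherit that calibration.
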