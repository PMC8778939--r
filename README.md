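# thermodox

Simulation of combination cancer therapy in a solid tumor: an intravenous
bolus of doxorubicin-loaded temperature-sensitive liposomes (TSL-Dox) whose
release is triggered by magnetic nanoparticle hyperthermia (MHT). The package
is aimed at computational tumor-physiology and drug-delivery modelers who
want a fast, fully scriptable 1-D spherically symmetric counterpart to the
usual finite-element treatment models, with every stage exposed as an R
function.

## The model

A spherical MNP injection site (radius 0.25 cm, magnetite volume fraction
3.3%) sits at the center of a 1 cm tumor surrounded by normal tissue out to
3 cm. Five coupled components are solved on one radial finite-volume grid:

1. **MNP power deposition** — linear-response (relaxation-loss) theory:

   `Q_MNP = phi mu0 chi0 Hm^2 f * (2 pi f tau_eff) / (1 + (2 pi f tau_eff)^2)`

   with Neel/Brown relaxation `tau_eff = tau_B tau_N / (tau_B + tau_N)`,
   `tau_B = 3 delta V_H / (kB T)`,
   `tau_N = (sqrt(pi)/2) tau0 e^Gamma / sqrt(Gamma)`,
   `Gamma = K_eff V_H / (kB T)`, and the field-dependent Langevin chord
   susceptibility `chi0`.

2. **Pennes bioheat** —
   `rho C dT/dt = div(k grad T) + rho_b C_b omega_b (T_b - T) + Q_m + alpha Q_MNP`,
   implicit in time, 37 C outer boundary, `alpha = 1` inside the injection
   region.

3. **Arrhenius thermal kill** — survival
   `DS = exp(-int A e^(-dE/RT) dt)` with `A = 1.98e106 1/s`,
   `dE = 6.67e5 J/mol`; heat-induced fraction of killed cells is `1 - DS`.

4. **Interstitial fluid mechanics** — steady Darcy flow
   `u = -kappa grad p` with the Starling source
   `phi_B = Lp S/V (P_b - p - sigma_s (pi_B - pi_i))`, no lymphatics inside
   the tumor, lymphatic drainage in normal tissue, `p = 0` at the outer
   boundary.

5. **Four-compartment drug transport** — encapsulated carrier (CL), free
   (CF), bound (CB) and internalized (CI) doxorubicin with mono-exponential
   plasma forcing, Patlak transvascular exchange, hindered-pore carrier
   permeability, temperature-triggered first-order release
   (`K_EL = 0.05409 1/s` at and above 42 C, zero below 39 C), receptor
   binding/unbinding and cellular uptake. Drug kill follows
   `FKC = 1 - exp(-omega CI)` with `omega = 0.6603 m3/mol`, and combined
   efficacy is the product of the independent survival fractions.

Scenario presets cover conventional chemotherapy, MHT alone at 11 and
13 kA/m (400 kHz, 60 min), and the combination protocol (TSL bolus, 9 h
delay, then MHT), plus sweeps over injection-to-AMF delay, dose, vessel-wall
pore size and field amplitude. See `vignette("thermodox-methods")` for the
modeling choices, the calibration of the unprinted constants, and known
limitations.

## Worked example

```r
library(thermodox)
res <- run_scenario(scenario_preset("combo_9h"))
summary(res)
#> Scenario mode: combination
#> FKC heat/drug/combined: 0.053 / 0.496 / 0.508
#> End-of-AMF temperatures (C): center 44.71, injection border 44.70, tumor border 38.45
#> Peak tumor-mean internalized drug: 1.41 mol/m3 at 72.0 h
```

Reading: after a unit bolus (Cp0 = 1 mol/m3) and one hour of 13 kA/m heating
applied 9 h post-injection, the hot core triggers liposomal release across
roughly half the tumor volume; internalized doxorubicin accumulates to a
tumor-mean 1.41 mol/m3 by 72 h, killing ~50% of tumor cells, while heat
alone accounts for ~5%. `plot(res)` draws the temperature probes,
compartment time courses and the radial internalized-drug profile;
`write_scenario_outputs(res, "out/")` serializes `summary.json`, time-series
and radial-profile CSVs and the resolved configuration.

Scenarios are plain YAML documents (`load_scenario()`, `scenario_to_yaml()`);
a thin command-line front end ships in `inst/cli/thermodox.R`:

```sh
Rscript inst/cli/thermodox.R sweep --axis delay --values 9,16,24,48 --out out/
```

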