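Package: thermodox
Title: Coupled Magnetic Hyperthermia and Thermosensitive Liposome Drug Delivery Simulation in Solid Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates combination cancer therapy in which an intravenous bolus of
    doxorubicin-loaded temperature-sensitive liposomes (TSL-Dox) is triggered by
    magnetic nanoparticle hyperthermia (MHT) inside a spherically symmetric solid
    tumor. Couples Rosensweig linear-response power deposition of superparamagnetic
    nanoparticles under an alternating magnetic field, the transient Pennes bioheat
    equation with Arrhenius thermal cell-kill kinetics, steady Darcy-Starling
    interstitial fluid mechanics, a temperature-triggered four-compartment drug
    transport model (encapsulated, free, bound, internalized), and an exponential
    dose-response model for the fraction of killed cells. Ships preset treatment
    scenarios (chemotherapy only, hyperthermia only, combination) and parameter
    sweeps over injection timing, dose, and vessel-wall pore size.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
Config/testthat/edition: 3
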