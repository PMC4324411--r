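Package: warfinr
Title: Warfarin Dose Individualization with a KPD Transit-Compartment INR Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the INR response to warfarin with a
    kinetic-pharmacodynamic (KPD) model in which the dose rate drives a
    sigmoid inhibition of coagulation-factor synthesis through two parallel
    three-compartment transit chains. Provides a priori maintenance-dose
    estimation for a target INR from patient covariates (age, bodyweight,
    CYP2C9 and VKORC1 genotype, baseline INR), INR prediction for arbitrary
    regimens including loading doses, and a posteriori Bayesian (MAP) dose
    revision from observed dosing histories and INRs, with 90 percent
    prediction bands from a Laplace approximation. Population parameters are
    supplied through a configuration file; a clearly labelled demo parameter
    set (not clinically valid) ships for testing. Includes a synthetic-patient
    generator for parameter-recovery and band-coverage experiments, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
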