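Package: meropk
Title: Population Pharmacokinetics and Dosing Simulation of Meropenem
    During ECMO and CRRT
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-compartment population pharmacokinetic model of meropenem
    in critically ill adults on veno-arterial ECMO, with continuous renal
    replacement therapy (CRRT) as a covariate on clearance. Provides
    closed-form infusion kinetics with multi-dose superposition, Monte
    Carlo simulation of probability of target attainment (PTA) for
    %fT>MIC targets across intermittent, extended and continuous infusion
    regimens, dosing-nomogram construction, synthetic sparse-sampling
    study generation, FOCE-type nonlinear mixed-effects estimation with
    likelihood-ratio covariate testing, nonparametric bootstrap
    confidence intervals, and prediction-corrected visual predictive
    checks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    deSolve,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
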