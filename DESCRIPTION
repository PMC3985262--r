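Package: patchpk
Title: One-Compartment Pharmacokinetics of Transdermal Contraceptive Patches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates serum concentrations of norelgestromin (NGMN) and
    ethinylestradiol (EE) released from a weekly transdermal contraceptive
    patch using a one-compartment model with an exponentially attenuating
    absorption rate and first-order elimination. Provides an event-driven
    regimen representation for compliant and non-compliant wear (delayed
    replacement, partial or total detachment), a forward-difference
    integrator with a piecewise closed-form solution as accuracy oracle,
    estimation of the elimination constant by log-linear regression of the
    post-removal decay and of the absorption attenuation constant by bounded
    least squares, summary pharmacokinetic metrics (plateau concentration,
    weekly AUC, therapeutic-window statistics), a synthetic sparse-sampling
    data generator with multiplicative lognormal noise, and a small
    configuration-driven pipeline with CSV/JSON/YAML interfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
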