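Package: afcea
Title: Cost-Effectiveness Modelling of Clinical Decision Support for
    Anticoagulation in Atrial Fibrillation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A lifetime Markov cohort state-transition model for evaluating
    the cost-effectiveness of a clinical decision support (CDS) system that
    increases adherence to guideline-recommended anticoagulation in atrial
    fibrillation. Tracks ischaemic stroke, intracranial haemorrhage, systemic
    embolism, myocardial infarction and major bleeding under treatment-specific
    relative risks, accumulates discounted costs and quality-adjusted life
    years with half-cycle correction, and reports incremental
    cost-effectiveness ratios. Includes probabilistic sensitivity analysis
    with role-specific parameter distributions, one-way (tornado) analysis,
    time-horizon, treatment-effect, implementation-cost and risk-profile
    scenario analyses, a threshold analysis for the maximum acceptable CDS
    price, a synthetic parameter generator for fully reproducible runs, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
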