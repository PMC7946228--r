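Package: dsrt
Title: Drug Sensitivity Screening, Growth-Rate-Corrected Dose Response and
    Response Biomarker Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis chain for multi-dose cell-line drug sensitivity
    screens: control-based normalization of 384-well plate reads with
    z'-factor and SSMD plate quality control, monotone-constrained
    five-point viability profiles scored by area under the log-dose
    curve, growth-kinetics calling of growth-reducing and
    growth-arresting concentrations from live-cell confluence series,
    growth-rate-corrected (GR) dose-response fitting with GR50
    extraction, and expression biomarker discovery by rank correlation
    with leave-one-out cross-validation and pre-ranked gene-set
    enrichment. Includes a synthetic-data generator with known ground
    truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    limma,
    emmeans,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
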