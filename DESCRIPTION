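Package: boolec
Title: Hybrid Boolean Signaling and Enzyme-Constrained Metabolic Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Couples a vector-based Boolean model of yeast nutrient signaling
    (Snf1, PKA, TORC1) to an enzyme-constrained model of central carbon
    metabolism through a signed transcription-factor-to-gene regulatory layer.
    Provides GECKO-style enzyme-constraint transformation of stoichiometric
    models, flux balance analysis with a protein pool constraint, parsimonious
    enzyme usage, enzyme usage variability analysis, regulated usage bounds,
    chemostat dilution-rate sweep simulation with deletion strains, flux
    control coefficients by finite perturbation, and model-evaluation
    statistics against proteomics tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    jsonlite,
    stats,
    utils
Suggests:
    pracma,
    xml2,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
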