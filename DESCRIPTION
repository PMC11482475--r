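Package: nanopotency
Title: Potency Analysis for In Vitro Nanoparticle Cytotoxicity Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Normalization, potency estimation and determinant analysis for
    multi-endpoint plate-based nanoparticle cytotoxicity screens. Raw plate
    signals are blank-corrected and converted to fold effects against
    zero-dose controls within each experiment; a one-parameter power-law
    dose-response model FE = (Dose + 1)^beta is fitted per particle and
    endpoint; absolute potency exponents are averaged across endpoints into
    a consensus potency used to rank particles. Additional tools associate
    potency with physicochemical descriptors (Pearson correlation, backward
    stepwise regression), run treatment/dose ANOVA with rank-transform
    fallback and Holm-Sidak multiple comparisons, analyse GSH/GSSG
    oxidative-stress fold changes, filter and cluster secreted-protein
    fold-change panels, and generate study-structured synthetic plate data
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
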