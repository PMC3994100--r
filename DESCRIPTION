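Package: daphniafeed
Title: Algal Dosing, Growth Statistics and Stable-Isotope Mixing for
    Zooplankton Feeding Experiments
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis toolkit for controlled feeding experiments in which a
    cladoceran grazer (e.g. Daphnia magna) is raised on one or two
    phytoplankton foods supplied at a fixed carbon concentration. Converts
    algal cell dimensions to per-cell carbon via log-log biovolume
    regressions and plans daily cell doses and stock injection volumes;
    compares growth endpoints (adult and offspring body length, offspring
    per adult, foregut cell counts) with nested ANOVA (beakers within
    treatment), one-way ANOVA, Tukey post-hoc tests and pooled t-tests from
    raw data or printed summary statistics; and estimates dietary source
    contributions with a two-source stable-isotope mixing model under an
    assumed trophic fractionation, with percentile-bootstrap uncertainty.
    A seeded generator produces complete synthetic experiments with the
    hierarchical structure the analysis assumes, so ingestion (gut-content
    split) and assimilation (isotopic mixing) can be set independently.
License: MIT
Encoding: UTF-8
Imports:
    rlang,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
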