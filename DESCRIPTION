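Package: dermafluor
Title: Dermatofluoroscopy Spectral Analysis of Pigmented Skin Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of spectrally resolved, two-photon-excited
    skin fluorescence measurements (dermatofluoroscopy) of pigmented skin
    lesions. Provides a fluorophore forward model (collagen second-harmonic
    line, NAD(P)H, keratin, melanin) for composing phenotype spectra, a
    synthetic cohort generator, preprocessing (signal-to-noise rejection,
    moving-average smoothing, maximum normalization), rule-based and
    margin-classifier assignment of per-spectrum spectral types, non-negative
    fluorophore unmixing with a difference-spectrum procedure, lesion-level
    malignancy scoring with a strict score-greater-than-28 excision rule, and
    cohort evaluation tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    pracma,
    e1071,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
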