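Package: vocalid
Title: Vocal Individuality Analysis of Mammalian Contact Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying individual acoustic signatures in mammalian
    contact calls, built around the workflow used for red deer (Cervus elaphus)
    mother and offspring vocalizations. Synthesizes harmonic calls with known
    ground-truth individuality, extracts a standard set of 14 temporal,
    fundamental-frequency and spectral-energy variables from waveforms,
    quantifies individual discriminability with linear discriminant analysis
    validated against a label-permutation chance level, compares oral and nasal
    call types with repeated-measures ANOVA and Yates-corrected chi-squared
    tests, and measures the between-year stability of individual vocal
    signatures by transferring discriminant functions across years.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    car
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
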