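Package: maldiprofiler
Title: Histology-Directed MALDI-IMS Proteomic Profiling Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis pipeline for histology-directed MALDI
    imaging mass-spectrometry profiling of annotated tissue spots:
    SNIP baseline removal, total-ion-current normalization, landmark-based
    mass-axis re-alignment, peak picking on the overall mean spectrum at a
    fixed signal-to-noise threshold, linear support-vector-machine spot
    classification with case-level majority voting, AUROC and volcano
    differential-peak statistics, and the accompanying clinical and
    immunohistochemistry comparison statistics (Wilcoxon-Mann-Whitney,
    Fisher exact, Kaplan-Meier and log-rank). Includes a synthetic-cohort
    generator emulating a two-class, two-compartment case/spot hierarchy
    so every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    e1071,
    survival,
    jsonlite,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    mzR
Config/testthat/edition: 3
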