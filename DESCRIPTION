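Package: cortexomics
Title: Spectral-Count Proteomics of the Actin Cortex with Shape and
    Timing Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Label-free quantification of cortex-enriched cellular
    fractions by MS/MS spectral counting. Implements total-count
    normalisation of protein spectral counts to a reference replicate,
    multi-criteria protein selection (minimum unique peptides, minimum
    mean normalised count in every condition), per-protein one-tailed
    Student t tests with volcano-table construction, curated-list
    candidate annotation and dual-evidence ranking, and the downstream
    validation readouts: polygon-based cell-shape morphometrics
    (area, perimeter, circularity, moment-ellipse aspect ratio),
    division-timing quantification from annotated frames, and qPCR
    relative expression by the delta-delta-Ct method. Includes a
    negative-binomial synthetic-data generator with planted
    differential effects for power and calibration studies, and an
    end-to-end pipeline driver with deterministic, seeded output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
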