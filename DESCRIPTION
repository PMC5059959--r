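Package: lome
Title: Low-Mass-Ion Discriminant Equations for MALDI-TOF Serum Screening
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constructs low-mass-ion discriminant equations (LOMEs) for
    disease screening from MALDI-TOF serum peak lists. Implements
    replicate-aware peak alignment on a reference mass axis with ppm
    tolerance, total-area-sum normalization, Pareto scaling, PCA-based
    discriminant analysis to derive per-ion weighting factors, two
    combinatorial search algorithms that select a small panel of
    discriminative ions, and a signed discriminant score classifier
    evaluated under a two-stage (trisected) training scheme. Ships a
    synthetic-cohort generator with planted discriminative ions so the
    whole pipeline is testable without access to instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    mzR,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
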