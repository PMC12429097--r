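Package: cdkl5ddg
Title: Thermodynamics-Based Reclassification of CDKL5 Missense Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Curates CDKL5 missense variant tables from heterogeneous source
    exports, scans substrate sequences for the kinase consensus phosphomotif
    RPX[S/T][A/G/P/S], aggregates multi-method folding and binding free-energy
    change (ddG) predictions into per-variant ddG_Fmax and ddG_Bmax statistics,
    derives midpoint thresholds from strictly annotated benign and pathogenic
    variants, reclassifies variants of uncertain or conflicting significance,
    partitions pathogenic variants by dominant thermodynamic mechanism, and
    evaluates third-party pathogenicity predictors with label-flip-invariant
    metrics. A synthetic-data module generates every input the pipeline
    consumes, with class-conditional ddG distributions and planted artefacts,
    so the full analysis is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    purrr,
    pROC,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
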