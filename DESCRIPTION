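Package: ampliscope
Title: In Silico PCR Evaluation of Clade-Restricted Metabarcoding Primers and
    Amplicon Pool Abundance Fidelity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing and evaluating clade-restricted metabarcoding
    assays, motivated by mosquito (Culicidae) surveillance with rDNA D2
    primers. Predicts PCR products from annotated reference sequences under a
    degenerate-base mismatch model with a strict 3'-terminal match criterion,
    summarises primer binding-site variation into position count matrices
    (sequence logos), scores taxonomic resolution of the predicted amplicons,
    assigns pooled reads by exact identity against a per-specimen variant
    library, and quantifies abundance fidelity of mock DNA pools
    (volume normalization, Best Estimate profiles, regression diagnostics,
    species dropout). A seeded generative model of pooled amplicon sequencing
    (amplifiability heterogeneity, degradation, bycatch saturation, carryover
    contamination) makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang (>= 1.0),
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
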