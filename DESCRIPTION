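Package: mcpkit
Title: Transcriptomic Marker Discovery and Microenvironment Cell Population Scoring
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Data-driven identification of transcriptomic markers (TM) of
    immune and stromal cell populations from a labeled compendium of
    purified-cell expression profiles, and per-sample abundance scoring of
    heterogeneous tissue transcriptomes from those marker sets. Marker
    screening combines a fold-change, a specific fold-change and a ROC AUC
    criterion computed against a pyramidal (rooted DAG) organization of cell
    population labels. The package also provides in-silico mRNA mixture
    simulation for quantitative validation, limit-of-detection estimation by
    inverse regression, and cohort-level utilities: per-dataset
    Z-standardization, cross-platform pan-cancer summaries, median-cut
    microenvironment classification and fixed-effect inverse-variance
    meta-analysis of per-dataset survival coefficients. A synthetic
    compendium generator makes the full pipeline testable without any
    external data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    tools
Suggests:
    survival,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
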