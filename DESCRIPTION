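Package: proteoturn
Title: Protein Turnover Kinetics and Proteome Aging Trajectories from
    Heavy-Leucine Metabolic Labeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for stable-isotope (2H3-leucine) metabolic
    labeling proteomics. Deconvolves peptide isotopologue envelopes into the
    fraction of newly synthesized protein with precursor-pool enrichment
    correction, scores envelope quality and applies the turnover-score
    filter, fits first-order half-lives per protein and treatment group,
    compares turnover slopes between groups by ANCOVA with peptide blocking,
    computes relative-abundance group contrasts with rank-based partial
    correlations that control shared ratio denominators, performs
    hypergeometric gene-set enrichment and hierarchical-clustering leaf
    ordering for heatmaps, and condenses abundance changes into a signed
    per-group aging-trajectory index. Includes a synthetic labeled-cohort
    generator with known ground truth emulating a four-group (young/old x
    wild-type/mCAT) cross-sectional labeling design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
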