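Package: citecompo
Title: Compositional Analysis of CITE-Seq Surface-Marker Data in Bone Marrow Engraftment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for antibody-derived-tag (surface marker)
    CITE-Seq analysis of bone marrow engraftment cohorts: droplet and gene
    quality-control filters, centered log-ratio normalization with
    half-quantification-limit zero replacement, a nested patient/batch
    harmonization that preserves between-group differences, variable-marker
    selection, PCA/UMAP embedding and kNN-graph Louvain clustering,
    per-patient cluster-abundance tables, and a compositional
    graph-disjointness test of abundance differences whose per-edge p-value
    threshold is calibrated by Monte-Carlo simulation to control the
    family-wise type-I error of graph disjointness. Includes a synthetic-data
    generator emulating a three-group (donor and two recipient strata)
    transplant cohort with patient and batch effects, repertoire diversity
    summaries, and the gating rules that precede per-cluster transcriptome
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    FNN,
    uwot,
    jsonlite,
    yaml,
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
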