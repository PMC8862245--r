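Package: panelgraph
Title: Pangenome Graph Coverage, Structural Variation and Methylation
    Analysis for Inbred Panels
Version: 0.1.0
Authors@R:
    person("Panelgraph", "Developers", email = "panelgraph@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for reference pangenome graphs built from a
    primary reference, alternative reference assemblies and a panel of
    inbred-line draft assemblies. Parses rGFA graphs with stable reference
    coordinates, computes per-sample length-normalised segment and junction
    coverage from GAF alignments, discovers divergent alternative paths and
    large-scale deletions from graph topology and coverage support,
    classifies annotated genes as core/fragmented/absent from core-segment
    exon coverage, annotates reference-anchored structural-variant call
    sets (pLI LOD scores, repeat overlap, singleton counts), and tests CpG
    islands for differential methylation from per-read log-likelihood
    ratios (Kruskal-Wallis with Benjamini-Hochberg FDR control). A
    synthetic-data module generates every input with recorded ground truth
    so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo: Rcpp
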