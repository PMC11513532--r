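Package: selexscope
Title: In Vivo SELEX Enrichment Analysis for Tissue-Targeting Aptamers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for in vivo SELEX (systematic evolution of
    ligands by exponential enrichment) next-generation sequencing experiments
    that select tissue-penetrating RNA aptamers. Extracts fixed-length
    variable regions from amplicon reads anchored by the library's constant
    regions, builds per-sample count tables across tissues and selection
    cycles, applies copy-number threshold and candidate filters, clusters
    sequences into families at a nucleotide-identity threshold, and
    quantifies cross-cycle and cross-tissue enrichment as pool fractions and
    fold changes. Companion validation tools compute control-normalized
    delta-Ct statistics from qPCR replicate tables with two-way ANOVA and
    Tukey comparisons, and estimate melting temperatures by fitting a
    Boltzmann sigmoid to circular-dichroism melt curves. A seeded simulator
    generates multi-round tissue-selective selection reads, qPCR tables and
    melt curves with ground-truth labels so the full pipeline can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    minpack.lm,
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
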