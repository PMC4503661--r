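Package: scc2xpress
Title: Expression, Splicing and Translational-Fidelity Analytics for
    Cohesin-Loader Mutants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for studies of the budding-yeast cohesin loader
    Scc2 and similar gene-expression mutants. Implements strand-aware metagene
    profiling of ChIP-seq coverage around transcription start sites, a
    junction-based splicing-efficiency statistic (Percent Spliced Out, PSO)
    with per-unit ANOVA and Benjamini-Hochberg correction, MA-plot and
    hypergeometric enrichment summaries of expression tables, Kolmogorov-
    Smirnov comparison of flow-cytometry fluorescence distributions with a
    replicate-baseline decision rule, dual-luciferase calculators for IRES
    activity, programmed ribosomal frameshifting and stop-codon readthrough,
    and sliding-window estimation of maximal specific growth rates from OD
    curves. A seeded synthetic-data module emulates every input class so the
    full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    GenomeInfoDb,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
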