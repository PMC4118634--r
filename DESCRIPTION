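Package: medipr
Title: MeDIP-Seq Methylome Profiling and Parent-Hybrid Differential
    Methylation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for comparative MeDIP-Seq (methylated DNA
    immunoprecipitation sequencing) methylome analysis of parental lines
    and their F1 hybrids: mapping summaries, per-million normalized 100-kb
    window coverage tracks, CG/CHG/CHH cytosine-context coverage
    statistics, read and peak fractions over genomic features, repeats and
    CpG islands, 20/40/20 binned metaprofiles, differential-methylation
    gene calling by chi-square testing on merged peak regions,
    hypergeometric term enrichment with Benjamini-Hochberg adjustment, and
    better-parent heterosis indices for growth traits. A self-contained
    MeDIP read simulator with exported ground truth (toy genome,
    annotation, per-line methylomes with additive or non-additive hybrid
    rules) makes the whole chain testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    data.table,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
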