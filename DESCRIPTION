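Package: exonconcord
Title: Exon-Level Concordance Between RNA-Seq and Exon Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for fine-grained, exon-level comparison of RNA-Seq read
    counts with exon microarray detection calls. Implements expected-error
    read filtering, exact-match 50-mer genome mappability profiling,
    mappability-corrected RPKM-style expression, a modified Matthews
    correlation correspondence score with Present/Absent threshold grids,
    the Audic-Claverie Poisson test for two-sample count data with
    exon-length bias diagnostics, exon-exon junction database construction
    and read mapping (known and permuted putative junctions), and discovery
    of novel transcribed loci from read clusters. Ships a synthetic-data
    generator with known truth (strand-aware 50-base reads, duplicated
    segments, a silent chromosome, planted novel junctions, triplicate
    array signals with detection p-values) so every stage can be exercised
    and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
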