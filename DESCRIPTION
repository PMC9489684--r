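Package: triosv
Title: Trio-Based Structural Variant Panel Construction and Quality Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds nonredundant structural-variant (SV) panels from
    per-sample deletion/insertion calls by distance- and type-aware
    clustering, computes founder-based allele frequencies and minor-allele
    frequency categories, profiles genotype quality through Mendelian
    inheritance errors in parent-offspring trios, tests genomic-feature
    enrichment by positional randomization, compares allele-frequency
    panels across cohorts, and summarises long-read sequencing quality
    (N50, mean read quality, alignment error profiles). Includes a
    synthetic trio-cohort generator so the full pipeline is exercisable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    vcfR,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    BiocGenerics,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
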