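Package: meltdownr
Title: Genomic Defect Census for Small and Declining Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and tallies putatively detrimental genomic defects from
    whole-genome resequencing summaries of diploid individuals: deletions
    called from read-depth change-point likelihood ratios, candidate
    retrogenes from exon-exon junction reads, and coding-effect
    classification of SNPs (synonymous, non-synonymous, premature stop)
    with ancient-DNA deamination-damage filtering and per-class
    heterozygosity (Hn, Hs). Includes a forward Wright-Fisher simulator of
    neutral and selected site classes under a piecewise population-size
    trajectory with a gamma distribution of fitness effects, a
    synthetic-data generator with planted truth sets for end-to-end
    validation, and census reporting with chi-squared and rank-sum
    comparisons.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
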