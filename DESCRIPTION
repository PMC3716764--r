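Package: wgaconcord
Title: Concordance Evaluation of Variant Callsets from Whole-Genome-Amplified DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates single-sample variant callsets derived from
    whole-genome-amplified (WGA) DNA against callsets from genomic DNA of the
    same individual, restricted to capture targets. Implements post-call hard
    filtering of SNP and INDEL calls, site-level Venn analysis, genotype
    concordance via non-reference sensitivity (NRS) and non-reference
    discrepancy (NRD), transition/transversion and dbSNP summaries, GC-binned
    coverage and concordance, pairwise Fisher exact tests of reference/alternate
    allele-combination bias with Bonferroni correction, bootstrap read
    downsampling across a coverage ladder, and validation of sequencing
    genotypes against SNP-array genotypes. Ships seeded synthetic-data
    generators with programmed joint genotype distributions so every stage can
    be exercised end-to-end with a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
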