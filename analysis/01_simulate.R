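#!/usr/bin/env Rscript
# Generate the synthetic paired-callset study: capture targets with a
# realistic GC spread, a reference sequence, evaluation (WGA) and comparison
# (genomic) callsets drawn from the programmed joint genotype distribution,
# per-target coverage with a GC penalty, a read-placement table, and a
# SNP-array genotype table. All downstream drivers read these files.

suppressMessages(library(wgaconcord))

out <- "results/fixtures"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- synthetic_config(
  seed = 101L,
  n_targets = 200L,
  n_snv = 5000L, n_indel = 500L,
  # inject a small fraction of hard-filter failures so the filtering stage
  # has work to do
  filter_fail = list(LOW_DP = 0.01, LOW_QUAL = 0.005, STRAND_BIAS = 0.005,
                     MQ0_FRACTION = 0.005)
)

tg <- generate_targets(cfg)
pc <- generate_paired_callsets(cfg, tg)
cr <- generate_coverage_and_reads(cfg, tg, pc$truth)
ar <- generate_array(cfg, tg, pc$truth)

write_bed(tg$targets, file.path(out, "targets.bed"))
Biostrings::writeXStringSet(tg$reference, file.path(out, "reference.fa"))
write_vcf(pc$eval_records, file.path(out, "eval_raw.vcf"), sample = "WGA")
write_vcf(pc$comp_records, file.path(out, "comp_raw.vcf"), sample = "GENOMIC")
write.table(pc$truth, file.path(out, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cr$coverage, file.path(out, "coverage.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cr$reads, file.path(out, "reads.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_array_table(ar$array, file.path(out, "array.tsv"))
write.table(ar$ref_alleles, file.path(out, "array_ref_alleles.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf(
  "generated %d targets spanning %d bp, %d evaluation and %d comparison records,\n%d reads, %d array markers (programmed SNP NRS %.2f%%, NRD %.2f%%)\n",
  nrow(tg$targets), target_span(tg$targets),
  nrow(pc$eval_records), nrow(pc$comp_records),
  nrow(cr$reads), nrow(ar$array),
  attr(cfg$joint_snv, "nrs"), attr(cfg$joint_snv, "nrd")))
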