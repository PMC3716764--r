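#!/usr/bin/env Rscript
# GC structure of the capture targets: per-target GC%, quartile binning,
# per-bin coverage boxplot tables, per-bin NRS/NRD, and windowed GC of the
# reference for comparison.

suppressMessages(library(wgaconcord))

fx <- "results/fixtures"
out <- "results"

targets <- read_bed(file.path(fx, "targets.bed"))
gc <- target_gc(targets, file.path(fx, "reference.fa"))
qb <- quartile_bins(gc$gc_percent)
gc$bin <- qb$bin
write.table(gc, file.path(out, "target_gc.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("target GC quartiles: Q1 %.1f%%, median %.1f%%, Q3 %.1f%%\n",
            qb$edges["Q1"], qb$edges["Q2"], qb$edges["Q3"]))

coverage <- read.table(file.path(fx, "coverage.tsv"), header = TRUE,
                       sep = "\t", stringsAsFactors = FALSE)
pbc <- per_bin_coverage(qb$bin, coverage)
write.table(pbc, file.path(out, "coverage_by_gc_bin.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
ev_med <- pbc[pbc$callset == "eval", ]
cat(sprintf("evaluation median coverage by GC bin: %s\n",
            paste(sprintf("bin%d=%.0fx", ev_med$bin, ev_med$median),
                  collapse = ", ")))

merged <- read.table(file.path(out, "merged_sites.tsv"), header = TRUE,
                     sep = "\t", stringsAsFactors = FALSE)
pbn <- per_bin_concordance(qb$bin, targets, merged)
write.table(pbn, file.path(out, "concordance_by_gc_bin.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
snp <- pbn[pbn$vclass == "SNP", ]
cat(sprintf("SNP NRD by GC bin: %s\n",
            paste(sprintf("bin%d=%.2f%%", snp$bin, snp$nrd),
                  collapse = ", ")))

ref <- Biostrings::readDNAStringSet(file.path(fx, "reference.fa"))
wgc <- windowed_gc(ref[[1]], window = 10000, step = 5000)
write.table(wgc, file.path(out, "windowed_gc.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("%d reference windows (10 kb / 5 kb step)\n", nrow(wgc)))
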