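#!/usr/bin/env Rscript
# Partition merged SNP sites into the four concordance categories, tabulate
# the six ref/alt allele combinations per category, and test for allele
# bias with pairwise Fisher exact tests under Bonferroni correction.

suppressMessages(library(wgaconcord))

out <- "results"
merged <- read.table(file.path(out, "merged_sites.tsv"), header = TRUE,
                     sep = "\t", stringsAsFactors = FALSE)

category <- categorize_sites(merged, mode = "four")
sp <- allele_spectrum(merged, category)
write.table(sp$counts, file.path(out, "allele_spectrum_counts.tsv"),
            sep = "\t", quote = FALSE, col.names = NA)
write.table(round(sp$proportions, 4),
            file.path(out, "allele_spectrum_proportions.tsv"),
            sep = "\t", quote = FALSE, col.names = NA)

res <- pairwise_bias_test(sp)
write.table(res, file.path(out, "allele_bias_tests.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

n_sig <- sum(res$significant)
cat(sprintf("category sizes: %s\n",
            paste(rownames(sp$counts), rowSums(sp$counts),
                  collapse = ", ", sep = "=")))
cat(sprintf("%d of %d pairwise tests significant at alpha = 0.05\n",
            n_sig, nrow(res)))
if (n_sig == 0) {
  cat("no evidence of allele-combination bias between categories\n")
}
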