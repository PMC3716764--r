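#!/usr/bin/env Rscript
# Validate the evaluation (WGA) sequencing SNP genotypes against the
# SNP-array genotypes: target-overlap and confidence filtering, A/B allele
# resolution, three-category concordance, and the array-mode allele
# spectrum with bias tests.

suppressMessages({library(wgaconcord); library(jsonlite)})

fx <- "results/fixtures"
out <- "results"

targets <- read_bed(file.path(fx, "targets.bed"))
ev <- read_vcf(file.path(fx, "eval_filtered.vcf"))
ev_pass <- ev[ev$filter == "PASS", ]; class(ev_pass) <- class(ev)
array <- read_array_table(file.path(fx, "array.tsv"))
ref_alleles <- read.table(file.path(fx, "array_ref_alleles.tsv"),
                          header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)

val <- validate_against_array(ev_pass, array, targets, ref_alleles)

write.table(val$matrix, file.path(out, "array_concordance_matrix.tsv"),
            sep = "\t", quote = FALSE, col.names = NA)
write.table(val$sites, file.path(out, "array_validated_sites.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(val$spectrum$counts,
            file.path(out, "array_allele_spectrum.tsv"),
            sep = "\t", quote = FALSE, col.names = NA)
write_json(list(nrs = val$nrs, nrd = val$nrd,
                exclusions = as.list(val$exclusions)),
           file.path(out, "array_validation_metrics.json"),
           auto_unbox = TRUE, digits = 6, pretty = TRUE)

cat(sprintf("validated %d array sites: NRS %.2f%%, NRD %.2f%%\n",
            nrow(val$sites), val$nrs, val$nrd))
cat("exclusions:", paste(names(val$exclusions), val$exclusions,
                         sep = "=", collapse = ", "), "\n")

if (sum(rowSums(val$spectrum$counts) > 0) >= 2) {
  res <- pairwise_bias_test(val$spectrum)
  write.table(res, file.path(out, "array_allele_bias_tests.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%d of %d array-mode pairwise tests significant\n",
              sum(res$significant), nrow(res)))
}
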