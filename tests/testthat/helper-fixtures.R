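# Compact builders for toy callsets used across test files.

snp_record <- function(pos, genotype, ref = "A", alt = "G", id = NA,
                       qual = 100, depth = 50, mq0 = 0, qd = 12,
                       hrun = 1, sb = -2, filter = "PASS", chrom = "chr12") {
  variant_records(chrom = chrom, pos = pos, ref = ref, alt = alt,
                  genotype = genotype, id = id, qual = qual, depth = depth,
                  mq0 = mq0, qd = qd, hrun = hrun, sb = sb,
                  vclass = "SNP", filter = filter)
}

indel_record <- function(pos, genotype, ref = "A", alt = "AT", id = NA,
                         qual = 100, depth = 50, mq0 = 0, sb = -2,
                         filter = "PASS", chrom = "chr12") {
  variant_records(chrom = chrom, pos = pos, ref = ref, alt = alt,
                  genotype = genotype, id = id, qual = qual, depth = depth,
                  mq0 = mq0, qd = 12, hrun = 1, sb = sb,
                  vclass = "INDEL", filter = filter)
}

bind_records <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  rownames(out) <- NULL
  class(out) <- c("variant_records", "data.frame")
  out
}

# One record violating each boundary of each SNP/INDEL filter term, plus
# clean records; the expected pass set is evaluated by hand from the filter
# expressions.
boundary_fixture <- function() {
  bind_records(
    snp_record(100, "HET"),                                   # clean SNP
    snp_record(110, "HET", depth = 4, mq0 = 0),               # DP < 5
    snp_record(120, "HET", qual = 29.9),                      # QUAL < 30
    snp_record(130, "HET", qd = 4.9),                         # QD < 5
    snp_record(140, "HET", hrun = 6),                         # HRun > 5
    snp_record(150, "HET", sb = -0.10),                       # SB >= -0.10 (inclusive)
    snp_record(160, "HET", depth = 1000, mq0 = 51),           # MQ0/DP = 0.051
    snp_record(170, "HOM_ALT"),                               # clean SNP
    indel_record(200, "HET"),                                 # clean INDEL
    indel_record(210, "HET", qual = 9.9),                     # QUAL < 10
    indel_record(220, "HET", sb = -1.0),                      # SB >= -1.0 (inclusive)
    indel_record(230, "HET", depth = 100, mq0 = 6)            # MQ0/DP = 0.06
  )
}

# one wide target covering the toy positions
toy_targets <- function(chrom = "chr12", start = 0L, end = 100000L) {
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}
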