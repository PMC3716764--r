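#' Read a SNP-array genotype table
#'
#' Tab-separated table with a header naming the six fields `marker`, `chrom`,
#' `pos` (1-based), `allele_a`, `allele_b`, `call`, `confidence`. Calls are
#' `AA`, `AB`, `BB` in the array's A/B allele frame, or a no-call (accepted
#' spellings: `NoCall`, `NO_CALL`, `NC`, `---`). Confidence is the
#' genotype-caller score in [0, 1] (Birdseed scores: lower is better).
#'
#' @param path Path to the table.
#' @return data.frame with columns `marker`, `chrom`, `pos`, `allele_a`,
#'   `allele_b`, `call` (normalized to `AA`/`AB`/`BB`/`NO_CALL`),
#'   `confidence`.
#' @export
read_array_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("marker", "chrom", "pos", "allele_a", "allele_b", "call",
            "confidence")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("array table missing column(s): ", paste(missing, collapse = ", "))
  }
  df <- df[, need]
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  nc <- df$call %in% c("NoCall", "NO_CALL", "NC", "---")
  df$call[nc] <- "NO_CALL"
  if (!all(df$call %in% c("AA", "AB", "BB", "NO_CALL"))) {
    stop("unrecognized array call value(s) in ", path)
  }
  if (any(df$allele_a == df$allele_b)) {
    stop("array marker with identical A/B alleles in ", path)
  }
  if (any(is.na(df$confidence) | df$confidence < 0 | df$confidence > 1)) {
    stop("array confidence outside [0, 1] in ", path)
  }
  df
}

#' Write a SNP-array genotype table
#'
#' Internal counterpart of [read_array_table()]; used for round-trip tests
#' and by the synthetic generator.
#'
#' @param records Array genotype data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_array_table <- function(records, path) {
  need <- c("marker", "chrom", "pos", "allele_a", "allele_b", "call",
            "confidence")
  utils::write.table(records[, need], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
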