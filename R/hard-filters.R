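#' Default hard-filter thresholds
#'
#' The post-call hard-filter expressions applied to SNP and INDEL calls. A
#' SNP fails when any of these holds:
#' `MQ0/DP > 0.05`, `DP < 5`, `QUAL < 30`, `QD < 5`, `HRun > 5`,
#' `SB >= -0.10`. An INDEL fails when any of `MQ0/DP > 0.05`, `SB >= -1.0`,
#' `QUAL < 10` holds. Inequalities are exactly as written: strict for `<`
#' and `>`, inclusive for `>=` on strand bias.
#'
#' @return Named list of thresholds with elements `snp` and `indel`.
#' @export
filter_thresholds <- function() {
  list(
    snp = list(mq0_frac = 0.05, min_dp = 5, min_qual = 30.0, min_qd = 5.0,
               max_hrun = 5.0, sb_ge = -0.10),
    indel = list(mq0_frac = 0.05, sb_ge = -1.0, min_qual = 10.0)
  )
}

# Vectorized per-term failure flags. Missing annotation (NA) skips the term;
# DP = 0 skips the MQ0 fraction (division guard) and necessarily fails
# LOW_DP. Returns a logical matrix (rows = records, cols = terms) plus a
# count of skipped term evaluations.
term_failures <- function(records, vclass, thresholds = filter_thresholds()) {
  n <- nrow(records)
  terms <- c("MQ0_FRACTION", "LOW_DP", "LOW_QUAL", "LOW_QD", "HRUN",
             "STRAND_BIAS")
  f <- matrix(FALSE, nrow = n, ncol = length(terms),
              dimnames = list(NULL, terms))
  if (n == 0L) {
    attr(f, "n_skipped") <- 0L
    return(f)
  }
  th <- thresholds[[tolower(vclass)]]
  dp <- records$depth; m0 <- records$mq0
  chk <- function(x) !is.na(x)  # term evaluable?
  skipped <- 0L

  mq0_ok <- chk(dp) & chk(m0) & !is.na(dp) & dp > 0L
  f[, "MQ0_FRACTION"] <- mq0_ok & (m0 / dp) > th$mq0_frac
  skipped <- skipped + sum(!mq0_ok)

  if (vclass == "SNP") {
    f[, "LOW_DP"] <- chk(dp) & dp < th$min_dp
    skipped <- skipped + sum(!chk(dp))
    f[, "LOW_QD"] <- chk(records$qd) & records$qd < th$min_qd
    skipped <- skipped + sum(!chk(records$qd))
    f[, "HRUN"] <- chk(records$hrun) & records$hrun > th$max_hrun
    skipped <- skipped + sum(!chk(records$hrun))
  } else {
    # no DP term for INDELs, but DP = 0 still fails as a division guard
    f[, "LOW_DP"] <- chk(dp) & dp == 0L
  }
  f[, "LOW_QUAL"] <- chk(records$qual) & records$qual < th$min_qual
  skipped <- skipped + sum(!chk(records$qual))
  f[, "STRAND_BIAS"] <- chk(records$sb) & records$sb >= th$sb_ge
  skipped <- skipped + sum(!chk(records$sb))

  attr(f, "n_skipped") <- skipped
  f
}

filter_one <- function(record, vclass, thresholds) {
  f <- term_failures(as.data.frame(record), vclass, thresholds)
  failed <- colnames(f)[f[1L, ]]
  list(passed = length(failed) == 0L, failed_terms = failed)
}

#' Apply the SNP hard filter to one record
#'
#' @param record One-row `variant_records` data.frame with `vclass == "SNP"`.
#' @param thresholds Threshold list, see [filter_thresholds()].
#' @return List with `passed` (logical) and `failed_terms` (character vector
#'   of every violated term).
#' @export
apply_snp_filter <- function(record, thresholds = filter_thresholds()) {
  stopifnot(nrow(record) == 1L, record$vclass == "SNP")
  filter_one(record, "SNP", thresholds)
}

#' Apply the INDEL hard filter to one record
#'
#' @inheritParams apply_snp_filter
#' @return List with `passed` and `failed_terms`.
#' @export
apply_indel_filter <- function(record, thresholds = filter_thresholds()) {
  stopifnot(nrow(record) == 1L, record$vclass == "INDEL")
  filter_one(record, "INDEL", thresholds)
}

#' Filter a callset with the SNP/INDEL hard filters
#'
#' Applies the variant-class-appropriate filter expression to every record,
#' rewrites the `filter` column (`PASS` or semicolon-joined failed terms),
#' and tallies failures per term. A record can count toward several terms.
#' Filtering is a pure function of the record fields and is idempotent.
#'
#' @param records A `variant_records` data.frame (any mix of SNPs/INDELs).
#' @param thresholds Threshold list, see [filter_thresholds()].
#' @return List with `records` (all records, filter column set), `pass`
#'   (PASS-only subset), `summary` (named integer vector of per-term failure
#'   counts) and `n_skipped_terms` (count of term evaluations skipped because
#'   the annotation was missing).
#' @export
filter_callset <- function(records, thresholds = filter_thresholds()) {
  df <- as.data.frame(records)
  terms <- c("MQ0_FRACTION", "LOW_DP", "LOW_QUAL", "LOW_QD", "HRUN",
             "STRAND_BIAS")
  fail <- matrix(FALSE, nrow(df), length(terms),
                 dimnames = list(NULL, terms))
  skipped <- 0L
  for (vc in c("SNP", "INDEL")) {
    sel <- df$vclass == vc
    if (!any(sel)) next
    f <- term_failures(df[sel, , drop = FALSE], vc, thresholds)
    fail[sel, ] <- f
    skipped <- skipped + attr(f, "n_skipped")
  }
  filt <- apply(fail, 1L, function(r) {
    if (!any(r)) "PASS" else paste(terms[r], collapse = ";")
  })
  if (nrow(df) == 0L) filt <- character(0)
  df$filter <- filt
  class(df) <- c("variant_records", "data.frame")
  pass <- df[df$filter == "PASS", , drop = FALSE]
  rownames(pass) <- NULL
  class(pass) <- c("variant_records", "data.frame")
  list(records = df, pass = pass,
       summary = colSums(fail), n_skipped_terms = skipped)
}
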