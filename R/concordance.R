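#' Merge two PASS-only callsets over capture targets
#'
#' Builds the merged-site table from which the concordance matrix, Venn
#' partitions, NRS and NRD are derived. Sites are keyed by
#' `(chrom, pos, vclass)`. A site present in only one callset gets genotype
#' `HOM_REF` in the other (the caller emitted no record there) — distinct
#' from an explicitly emitted `./.` record, which is `NO_CALL`. Both reduce
#' NRS; only `NO_CALL` is excluded from NRD. Sites where neither genotype is
#' variant are never materialized. Reference-allele mismatches at a shared
#' key are excluded and counted (attribute `n_ref_conflicts`). Differing
#' alternate alleles at a shared key are retained with both alts recorded
#' and count as a genotype discordance downstream.
#'
#' @param eval_records,comp_records `variant_records` data.frames; must be
#'   PASS-only (records with any other filter status are rejected).
#' @param targets Optional normalized target data.frame; when given, records
#'   outside all targets are dropped before merging.
#' @return data.frame of merged sites with columns `chrom`, `pos`, `vclass`,
#'   `ref`, `alt_eval`, `alt_comp`, `alt` (comparison alt when present, else
#'   evaluation alt), `g_eval`, `g_comp`, `known` (dbSNP id present in
#'   either callset).
#' @export
merge_callsets <- function(eval_records, comp_records, targets = NULL) {
  prep <- function(df, side) {
    df <- as.data.frame(df)
    if (nrow(df) > 0L && any(df$filter != "PASS")) {
      stop(side, " callset is not PASS-only; run filter_callset() first")
    }
    if (!is.null(targets) && nrow(df) > 0L) {
      df <- df[pos_in_targets(df$chrom, df$pos, targets), , drop = FALSE]
    }
    if (nrow(df) == 0L) {
      return(data.frame(chrom = character(0), pos = integer(0),
                        vclass = character(0), ref = character(0),
                        alt = character(0), g = character(0),
                        known = logical(0), stringsAsFactors = FALSE))
    }
    out <- data.frame(chrom = df$chrom, pos = df$pos, vclass = df$vclass,
                      ref = df$ref, alt = df$alt, g = df$genotype,
                      known = !is.na(df$id), stringsAsFactors = FALSE)
    # collapse duplicate keys within one callset (split multi-allelics):
    # keep the most-variant genotype, join alts
    key <- paste(out$chrom, out$pos, out$vclass, sep = "\r")
    if (anyDuplicated(key)) {
      rank <- c(NO_CALL = 0L, HOM_REF = 1L, HET = 2L, HOM_ALT = 3L)
      sp <- split(seq_len(nrow(out)), key)
      rows <- vapply(sp, function(i) i[which.max(rank[out$g[i]])], 1L)
      alts <- vapply(sp, function(i)
        paste(unique(out$alt[i]), collapse = ","), "")
      known <- vapply(sp, function(i) any(out$known[i]), TRUE)
      out <- out[rows, , drop = FALSE]
      out$alt <- alts[paste(out$chrom, out$pos, out$vclass, sep = "\r")]
      out$known <- known[paste(out$chrom, out$pos, out$vclass, sep = "\r")]
    }
    out
  }
  ev <- prep(eval_records, "evaluation")
  cp <- prep(comp_records, "comparison")

  m <- merge(ev, cp, by = c("chrom", "pos", "vclass"), all = TRUE,
             suffixes = c("_eval", "_comp"))
  m$g_eval <- ifelse(is.na(m$g_eval), "HOM_REF", m$g_eval)
  m$g_comp <- ifelse(is.na(m$g_comp), "HOM_REF", m$g_comp)

  conflict <- !is.na(m$ref_eval) & !is.na(m$ref_comp) &
    m$ref_eval != m$ref_comp
  n_conflicts <- sum(conflict)
  if (n_conflicts > 0L) {
    warning(n_conflicts,
            " site(s) with mismatched reference alleles excluded from merge")
    m <- m[!conflict, , drop = FALSE]
  }

  out <- data.frame(
    chrom = m$chrom, pos = m$pos, vclass = m$vclass,
    ref = ifelse(is.na(m$ref_eval), m$ref_comp, m$ref_eval),
    alt_eval = m$alt_eval, alt_comp = m$alt_comp,
    alt = ifelse(is.na(m$alt_comp), m$alt_eval, m$alt_comp),
    g_eval = m$g_eval, g_comp = m$g_comp,
    known = (!is.na(m$known_eval) & m$known_eval) |
      (!is.na(m$known_comp) & m$known_comp),
    stringsAsFactors = FALSE
  )
  out <- out[is_variant(out$g_eval) | is_variant(out$g_comp), , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_ref_conflicts") <- n_conflicts
  out
}

#' Genotype concordance matrix
#'
#' 4x4 table of (evaluation genotype, comparison genotype) counts over the
#' merged sites. The (HOM_REF, HOM_REF) cell is structurally zero because
#' sites with no variant genotype are never materialized.
#'
#' @param merged Merged-site table from [merge_callsets()].
#' @return Integer matrix with genotype-state dimnames; rows = evaluation,
#'   columns = comparison.
#' @export
concordance_matrix <- function(merged) {
  lv <- genotype_states()
  tab <- table(factor(merged$g_eval, levels = lv),
               factor(merged$g_comp, levels = lv))
  m <- matrix(as.integer(tab), 4L, 4L, dimnames = list(eval = lv, comp = lv))
  m
}

#' Non-reference sensitivity (NRS)
#'
#' The percentage of comparison-callset variant sites that are also called
#' variant in the evaluation callset. Sites homozygous-reference or no-call
#' in the evaluation callset but variant in the comparison callset reduce
#' NRS.
#'
#' @param mat Concordance matrix from [concordance_matrix()].
#' @return Percentage in [0, 100], or `NA_real_` when the comparison callset
#'   has no variant sites (undefined).
#' @export
nrs <- function(mat) {
  v <- c("HET", "HOM_ALT")
  denom <- sum(mat[, v])
  if (denom == 0L) {
    warning("NRS undefined: comparison callset has no variant sites")
    return(NA_real_)
  }
  100 * sum(mat[v, v]) / denom
}

#' Non-reference discrepancy (NRD)
#'
#' The percentage of discordant genotypes among sites genotyped in both
#' callsets, excluding concordant homozygous-reference sites. `NO_CALL` in
#' either callset removes the site from both numerator and denominator.
#'
#' @param mat Concordance matrix from [concordance_matrix()].
#' @return Percentage in [0, 100], or `NA_real_` when no site is eligible.
#' @export
nrd <- function(mat) {
  called <- c("HOM_REF", "HET", "HOM_ALT")
  sub <- mat[called, called]
  denom <- sum(sub) - sub["HOM_REF", "HOM_REF"]
  if (denom == 0L) {
    warning("NRD undefined: no sites called in both callsets")
    return(NA_real_)
  }
  disc <- sum(sub) - sum(diag(sub))
  100 * disc / denom
}

#' Callset summary: counts, dbSNP fraction, TsTv ratios
#'
#' @param records PASS-only `variant_records` of a single variant class, or
#'   any data.frame with `ref`, `alt` and a dbSNP-membership indicator.
#' @param known Logical vector of dbSNP membership; defaults to
#'   `!is.na(records$id)`.
#' @return List with `n_variants`, `dbsnp_percent`, and (for SNPs)
#'   `tstv_overall`, `tstv_novel`, `tstv_known` (`NA_real_` when undefined,
#'   e.g. no transversions or no records).
#' @export
callset_summary <- function(records, known = NULL) {
  df <- as.data.frame(records)
  if (is.null(known)) known <- !is.na(df$id)
  n <- nrow(df)
  if (n == 0L) {
    return(list(n_variants = 0L, dbsnp_percent = NA_real_,
                tstv_overall = NA_real_, tstv_novel = NA_real_,
                tstv_known = NA_real_))
  }
  snp <- nchar(df$ref) == 1L & nchar(df$alt) == 1L &
    grepl("^[ACGT]$", df$ref) & grepl("^[ACGT]$", df$alt)
  list(
    n_variants = n,
    dbsnp_percent = 100 * sum(known) / n,
    tstv_overall = tstv_ratio(df$ref[snp], df$alt[snp]),
    tstv_novel = tstv_ratio(df$ref[snp & !known], df$alt[snp & !known]),
    tstv_known = tstv_ratio(df$ref[snp & known], df$alt[snp & known])
  )
}

#' Venn partition of two callsets by coordinate intersection
#'
#' Splits the merged sites into evaluation-only, comparison-only, and
#' intersection by site-level variant status, with a per-partition SNP
#' summary (count, dbSNP percent, TsTv overall/novel/known).
#'
#' @param merged Merged-site table from [merge_callsets()].
#' @return List with counts `n_eval_only`, `n_comp_only`, `n_intersection`
#'   and per-partition summaries `eval_only`, `comp_only`, `intersection`
#'   (SNP sites only, computed on the partition's own alternate alleles).
#' @export
venn_partition <- function(merged) {
  ev <- is_variant(merged$g_eval)
  cv <- is_variant(merged$g_comp)
  eval_only <- ev & !cv
  comp_only <- cv & !ev
  both <- ev & cv
  part_summary <- function(sel, alt_col) {
    sub <- merged[sel & merged$vclass == "SNP", , drop = FALSE]
    sub$alt <- sub[[alt_col]]
    sub <- sub[grepl("^[ACGT]$", sub$alt), , drop = FALSE]
    callset_summary(sub, known = sub$known)
  }
  list(
    n_eval_only = sum(eval_only),
    n_comp_only = sum(comp_only),
    n_intersection = sum(both),
    eval_only = part_summary(eval_only, "alt_eval"),
    comp_only = part_summary(comp_only, "alt_comp"),
    intersection = part_summary(both, "alt")
  )
}

#' Concordance report for a merged callset pair
#'
#' Convenience wrapper bundling the concordance matrix, NRS, NRD and the
#' Venn partition for one merged table.
#'
#' @param merged Merged-site table.
#' @param vclass Optional variant class (`"SNP"` or `"INDEL"`) to restrict
#'   to before computing.
#' @return List with `matrix`, `nrs`, `nrd`, `venn`, `n_sites`.
#' @export
report_concordance <- function(merged, vclass = NULL) {
  if (!is.null(vclass)) {
    merged <- merged[merged$vclass == vclass, , drop = FALSE]
  }
  mat <- concordance_matrix(merged)
  list(matrix = mat,
       nrs = suppressWarnings(nrs(mat)),
       nrd = suppressWarnings(nrd(mat)),
       venn = venn_partition(merged),
       n_sites = nrow(merged))
}
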