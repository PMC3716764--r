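#' Assign merged SNP sites to concordance categories
#'
#' Four-way mode (callset-vs-callset comparison):
#' * `COMP_UNIQUE` — comparison variant, evaluation HOM_REF or NO_CALL
#'   (these sites contribute to NRS loss);
#' * `EVAL_UNIQUE` — the symmetric case;
#' * `CONCORDANT` — both variant with equal genotype and equal alternate
#'   allele;
#' * `DISCORDANT` — both called variant but with unequal genotypes or
#'   unequal alternate alleles (NRD-contributing).
#'
#' Three-way mode (sequencing-vs-array validation; the comparison callset is
#' the array):
#' * `NRS_CONTRIBUTING` — array variant, sequencing HOM_REF or NO_CALL;
#' * `NRD_CONTRIBUTING` — both called, genotypes (or alts) unequal;
#' * `CONCORDANT` — both called and equal.
#' Sites where the array is NO_CALL and the sequencing call is variant fit
#' none of the three categories and are returned as `NA` (counted in
#' attribute `n_unclassified`).
#'
#' @param merged Merged-site table from [merge_callsets()]; SNP rows only
#'   are categorized (other rows get `NA`).
#' @param mode `"four"` or `"three"`.
#' @return Character vector of categories aligned with `merged` rows.
#' @export
categorize_sites <- function(merged, mode = c("four", "three")) {
  mode <- match.arg(mode)
  ev <- is_variant(merged$g_eval)
  cv <- is_variant(merged$g_comp)
  same_alt <- !is.na(merged$alt_eval) & !is.na(merged$alt_comp) &
    merged$alt_eval == merged$alt_comp
  out <- rep(NA_character_, nrow(merged))
  snp <- merged$vclass == "SNP"
  if (mode == "four") {
    out[snp & cv & !ev] <- "COMP_UNIQUE"
    out[snp & ev & !cv] <- "EVAL_UNIQUE"
    out[snp & ev & cv & merged$g_eval == merged$g_comp & same_alt] <- "CONCORDANT"
    out[snp & ev & cv & is.na(out)] <- "DISCORDANT"
  } else {
    called_both <- is_called(merged$g_eval) & is_called(merged$g_comp)
    out[snp & cv & !ev] <- "NRS_CONTRIBUTING"
    conc <- snp & called_both & ev & cv & merged$g_eval == merged$g_comp &
      same_alt
    out[conc] <- "CONCORDANT"
    disc <- snp & called_both & is.na(out)
    out[disc] <- "NRD_CONTRIBUTING"
    # remaining: eval variant, comp NO_CALL -> unclassifiable in this mode
  }
  attr(out, "n_unclassified") <- sum(is.na(out) & snp)
  out
}

#' Category names for a bias-test mode
#' @param mode `"four"` or `"three"`.
#' @return Character vector of category names.
#' @export
bias_categories <- function(mode = c("four", "three")) {
  mode <- match.arg(mode)
  if (mode == "four") {
    c("CONCORDANT", "COMP_UNIQUE", "DISCORDANT", "EVAL_UNIQUE")
  } else {
    c("CONCORDANT", "NRS_CONTRIBUTING", "NRD_CONTRIBUTING")
  }
}

#' Allele spectrum per concordance category
#'
#' Tabulates the six unordered reference/alternate allele combinations
#' within each concordance category.
#'
#' @param merged Merged-site table (SNP rows are used).
#' @param category Category per site, from [categorize_sites()].
#' @return List with `counts` (category x combination integer matrix) and
#'   `proportions` (same shape; rows of empty categories are `NA`).
#' @export
allele_spectrum <- function(merged, category) {
  keep <- !is.na(category) & merged$vclass == "SNP" &
    grepl("^[ACGT]$", merged$ref) & grepl("^[ACGT]$", merged$alt)
  combo <- allele_combination(merged$ref[keep], merged$alt[keep])
  cats <- unique(category[keep])
  cats <- cats[order(match(cats, c(bias_categories("four"),
                                   bias_categories("three"))))]
  counts <- table(factor(category[keep], levels = cats),
                  factor(combo, levels = allele_combinations()))
  counts <- matrix(as.integer(counts), nrow = length(cats),
                   dimnames = list(category = cats,
                                   combination = allele_combinations()))
  totals <- rowSums(counts)
  props <- counts / ifelse(totals == 0, NA_real_, totals)
  list(counts = counts, proportions = props)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact two-sided p-value by hypergeometric enumeration: the sum of the
#' point probabilities of all tables with the observed margins whose
#' probability does not exceed that of the observed table, with a relative
#' tolerance of 1e-7 on the comparison to guard floating-point ties.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value. A zero margin yields p = 1 with a warning.
#' @export
fisher_exact_2x2 <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == 2L), all(tab >= 0))
  a <- tab[1, 1]
  m <- sum(tab[1, ])          # row-1 margin
  n <- sum(tab[2, ])          # row-2 margin
  k <- sum(tab[, 1])          # column-1 margin
  if (m == 0 || n == 0 || k == 0 || sum(tab[, 2]) == 0) {
    warning("Fisher test on a table with a zero margin; p = 1")
    return(1)
  }
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(p, 1)
}

#' Pairwise Fisher exact tests of allele-combination bias
#'
#' For each of the six allele combinations (or a chosen one), tests every
#' unordered pair of concordance categories for a difference in that
#' combination's proportion: the 2x2 table is (combination count vs count of
#' all other combinations) x (category A vs category B). Raw p-values are
#' Bonferroni-adjusted and flagged at the significance level.
#'
#' @param spectrum Result of [allele_spectrum()] (its `counts` matrix is
#'   used), or a category x combination count matrix.
#' @param combination Optional single combination (e.g. `"C/G"`); default
#'   all six.
#' @param alpha Significance level for the flag (default 0.05).
#' @param bonferroni_scope `"pairs"` (default) multiplies each raw p by the
#'   number of category pairs within its combination;
#'   `"pairs_by_combinations"` multiplies by pairs x combinations tested.
#' @return data.frame with `combination`, `cat_a`, `cat_b`, `p_raw`, `p_adj`
#'   (capped at 1), `significant`.
#' @export
pairwise_bias_test <- function(spectrum, combination = NULL, alpha = 0.05,
                               bonferroni_scope = c("pairs",
                                                    "pairs_by_combinations")) {
  bonferroni_scope <- match.arg(bonferroni_scope)
  counts <- if (is.list(spectrum)) spectrum$counts else spectrum
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  cats <- rownames(counts)
  if (length(cats) < 2L) stop("need >= 2 categories with non-zero totals")
  combos <- if (is.null(combination)) colnames(counts) else combination
  stopifnot(all(combos %in% colnames(counts)))
  pairs <- utils::combn(cats, 2L)
  n_pairs <- ncol(pairs)
  n_tests <- switch(bonferroni_scope,
                    pairs = n_pairs,
                    pairs_by_combinations = n_pairs * length(combos))
  totals <- rowSums(counts)
  res <- do.call(rbind, lapply(combos, function(cb) {
    p_raw <- vapply(seq_len(n_pairs), function(j) {
      ca <- pairs[1, j]; cbn <- pairs[2, j]
      tab <- rbind(c(counts[ca, cb], totals[ca] - counts[ca, cb]),
                   c(counts[cbn, cb], totals[cbn] - counts[cbn, cb]))
      suppressWarnings(fisher_exact_2x2(tab))
    }, 1.0)
    data.frame(combination = cb, cat_a = pairs[1, ], cat_b = pairs[2, ],
               p_raw = p_raw, stringsAsFactors = FALSE)
  }))
  res$p_adj <- pmin(1, res$p_raw * n_tests)
  res$significant <- res$p_adj < alpha
  rownames(res) <- NULL
  res
}
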