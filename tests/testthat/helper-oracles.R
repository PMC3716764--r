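# Brute-force oracles that re-scan the merged site list row by row,
# independent of the matrix-based implementations they check.

oracle_matrix <- function(merged) {
  lv <- genotype_states()
  m <- matrix(0L, 4, 4, dimnames = list(eval = lv, comp = lv))
  for (i in seq_len(nrow(merged))) {
    m[merged$g_eval[i], merged$g_comp[i]] <- m[merged$g_eval[i],
                                               merged$g_comp[i]] + 1L
  }
  m
}

oracle_nrs <- function(merged) {
  den <- 0L; num <- 0L
  for (i in seq_len(nrow(merged))) {
    if (merged$g_comp[i] %in% c("HET", "HOM_ALT")) {
      den <- den + 1L
      if (merged$g_eval[i] %in% c("HET", "HOM_ALT")) num <- num + 1L
    }
  }
  if (den == 0L) NA_real_ else 100 * num / den
}

oracle_nrd <- function(merged) {
  den <- 0L; num <- 0L
  for (i in seq_len(nrow(merged))) {
    ge <- merged$g_eval[i]; gc <- merged$g_comp[i]
    if (ge == "NO_CALL" || gc == "NO_CALL") next
    if (ge == "HOM_REF" && gc == "HOM_REF") next
    den <- den + 1L
    if (ge != gc) num <- num + 1L
  }
  if (den == 0L) NA_real_ else 100 * num / den
}

oracle_venn <- function(merged) {
  eo <- 0L; co <- 0L; it <- 0L
  for (i in seq_len(nrow(merged))) {
    ev <- merged$g_eval[i] %in% c("HET", "HOM_ALT")
    cv <- merged$g_comp[i] %in% c("HET", "HOM_ALT")
    if (ev && cv) it <- it + 1L
    else if (ev) eo <- eo + 1L
    else if (cv) co <- co + 1L
  }
  c(n_eval_only = eo, n_comp_only = co, n_intersection = it)
}

# Build a merged-site-shaped table from genotype pairs alone (positions and
# alleles synthesized; both-nonvariant pairs are invalid input by the
# merged-table invariant and must not be supplied).
merged_from_pairs <- function(g_eval, g_comp, vclass = "SNP") {
  n <- length(g_eval)
  data.frame(
    chrom = rep("chrT", n), pos = seq_len(n), vclass = rep(vclass, n),
    ref = rep("A", n), alt_eval = rep("G", n), alt_comp = rep("G", n),
    alt = rep("G", n), g_eval = g_eval, g_comp = g_comp,
    known = rep(FALSE, n), stringsAsFactors = FALSE
  )
}

# All (g_eval, g_comp) pairs a merged table can contain (>= one variant).
valid_genotype_pairs <- function() {
  lv <- genotype_states()
  grid <- expand.grid(g_eval = lv, g_comp = lv, stringsAsFactors = FALSE)
  v <- c("HET", "HOM_ALT")
  grid[grid$g_eval %in% v | grid$g_comp %in% v, , drop = FALSE]
}
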