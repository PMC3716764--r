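#' Filter SNP-array genotype records for validation
#'
#' Keeps array markers that (a) lie inside a capture target and (b) satisfy
#' the confidence threshold. Birdseed-style confidence scores are better
#' when lower, so the default direction is `at-most`; `at-least` is exposed
#' because the opposite reading of the threshold exists.
#'
#' @param array_records data.frame from [read_array_table()].
#' @param targets Normalized target data.frame.
#' @param confidence_threshold Threshold on the confidence score
#'   (default 0.05).
#' @param direction `"at-most"` (default) retains `confidence <= threshold`;
#'   `"at-least"` retains `confidence >= threshold`.
#' @return Retained subset, with attribute `excluded` giving counts per
#'   exclusion reason (`off_target`, `confidence`).
#' @export
filter_array_sites <- function(array_records, targets,
                               confidence_threshold = 0.05,
                               direction = c("at-most", "at-least")) {
  direction <- match.arg(direction)
  on_target <- pos_in_targets(array_records$chrom, array_records$pos,
                              targets)
  conf_ok <- if (direction == "at-most") {
    array_records$confidence <= confidence_threshold
  } else {
    array_records$confidence >= confidence_threshold
  }
  keep <- on_target & conf_ok
  out <- array_records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- c(off_target = sum(!on_target),
                             confidence = sum(on_target & !conf_ok))
  out
}

#' Map array A/B calls onto the reference frame
#'
#' Resolves each marker's A/B alleles against the site's reference and
#' alternate alleles, directly or by reverse complement, and converts
#' `AA`/`AB`/`BB` calls to genotype states. Complement-ambiguous markers
#' (A/T and C/G allele pairs) cannot be strand-resolved and are excluded by
#' default rather than guessed; markers whose alleles do not match
#' `{ref, alt}` either way are excluded as allele conflicts.
#'
#' @param allele_a,allele_b Array allele bases per marker.
#' @param call Array calls (`AA`, `AB`, `BB`, `NO_CALL`).
#' @param ref,alt Reference and alternate base per marker (`alt` may be `NA`
#'   when the sequencing callset has no record; the non-reference array
#'   allele is then taken as the alternate).
#' @param exclude_ambiguous Drop A/T and C/G markers (default `TRUE`).
#' @return Character vector of genotype states, `NA` where the marker was
#'   excluded; attribute `n_excluded` gives counts
#'   (`complement_ambiguous`, `allele_conflict`).
#' @export
array_to_genotype <- function(allele_a, allele_b, call, ref, alt,
                              exclude_ambiguous = TRUE) {
  n <- length(call)
  stopifnot(length(allele_a) == n, length(allele_b) == n,
            length(ref) == n, length(alt) == n)
  out <- rep(NA_character_, n)
  ambiguous <- (allele_a == complement_base(allele_b))
  a <- allele_a; b <- allele_b
  alt_eff <- ifelse(is.na(alt),
                    ifelse(a == ref, b, a),
                    alt)
  direct <- (a == ref & b == alt_eff) | (a == alt_eff & b == ref)
  ca <- complement_base(a); cb <- complement_base(b)
  comp <- (ca == ref & cb == alt_eff) | (ca == alt_eff & cb == ref)
  use_comp <- !direct & comp
  a[use_comp] <- ca[use_comp]; b[use_comp] <- cb[use_comp]
  resolved <- direct | comp
  if (exclude_ambiguous) resolved <- resolved & !ambiguous
  n_amb <- sum(ambiguous & (direct | comp)) * exclude_ambiguous
  n_conf <- sum(!direct & !comp)

  hom_a <- ifelse(a == ref, "HOM_REF", "HOM_ALT")
  hom_b <- ifelse(b == ref, "HOM_REF", "HOM_ALT")
  g <- ifelse(call == "AA", hom_a,
              ifelse(call == "BB", hom_b,
                     ifelse(call == "AB", "HET", "NO_CALL")))
  out[resolved] <- g[resolved]
  attr(out, "n_excluded") <- c(complement_ambiguous = as.integer(n_amb),
                               allele_conflict = as.integer(n_conf))
  out
}

#' Validate sequencing genotypes against SNP-array genotypes
#'
#' The array is the comparison callset: array records are filtered to
#' targets and the confidence threshold, mapped to the reference frame, and
#' merged with the PASS-only sequencing SNP calls. The concordance engine
#' then yields the 4x4 matrix (array states on one axis), NRS and NRD, the
#' per-site three-way categories, and the three-category allele spectrum.
#'
#' @param seq_records PASS-only `variant_records` (SNPs are used).
#' @param array_records data.frame from [read_array_table()].
#' @param targets Normalized target data.frame.
#' @param ref_alleles Optional data.frame `chrom`, `pos`, `ref`, `alt`
#'   supplying the reference frame for markers absent from the sequencing
#'   callset (e.g. from the marker annotation). Markers with no reference
#'   information from either source are dropped and counted.
#' @param confidence_threshold,direction Passed to [filter_array_sites()].
#' @return List with `matrix`, `nrs`, `nrd`, `sites` (merged table plus
#'   `category`), `spectrum`, and `exclusions` (named counts from every
#'   filtering step).
#' @export
validate_against_array <- function(seq_records, array_records, targets,
                                   ref_alleles = NULL,
                                   confidence_threshold = 0.05,
                                   direction = "at-most") {
  seq_df <- as.data.frame(seq_records)
  seq_df <- seq_df[seq_df$vclass == "SNP", , drop = FALSE]
  arr <- filter_array_sites(array_records, targets,
                            confidence_threshold, direction)
  excl <- attr(arr, "excluded")

  # reference frame per marker: sequencing record first, then annotation
  key <- function(chrom, pos) paste(chrom, pos, sep = ":")
  ref_map <- stats::setNames(seq_df$ref, key(seq_df$chrom, seq_df$pos))
  alt_map <- stats::setNames(seq_df$alt, key(seq_df$chrom, seq_df$pos))
  k <- key(arr$chrom, arr$pos)
  ref <- unname(ref_map[k])
  alt <- unname(alt_map[k])
  if (!is.null(ref_alleles)) {
    ka <- key(ref_alleles$chrom, ref_alleles$pos)
    miss <- is.na(ref)
    ref[miss] <- stats::setNames(ref_alleles$ref, ka)[k[miss]]
    alt[miss] <- stats::setNames(ref_alleles$alt, ka)[k[miss]]
  }
  no_ref <- is.na(ref)
  excl <- c(excl, no_reference = sum(no_ref))
  arr <- arr[!no_ref, , drop = FALSE]
  ref <- ref[!no_ref]; alt <- alt[!no_ref]

  g_array <- array_to_genotype(arr$allele_a, arr$allele_b, arr$call,
                               ref, alt)
  excl <- c(excl, attr(g_array, "n_excluded"))
  ok <- !is.na(g_array)
  arr_records <- variant_records(
    chrom = arr$chrom[ok], pos = arr$pos[ok], ref = ref[ok],
    alt = ifelse(is.na(alt[ok]),
                 ifelse(arr$allele_a[ok] == ref[ok],
                        arr$allele_b[ok], arr$allele_a[ok]),
                 alt[ok]),
    genotype = g_array[ok], id = arr$marker[ok], filter = "PASS"
  )
  seq_pass <- seq_df
  class(seq_pass) <- c("variant_records", "data.frame")
  merged <- merge_callsets(seq_pass, arr_records, targets)
  # the validation universe is the retained array markers: sequencing calls
  # at positions the array does not assay are out of scope
  marker_key <- key(arr_records$chrom, arr_records$pos)
  in_universe <- key(merged$chrom, merged$pos) %in% marker_key
  n_off_marker <- sum(!in_universe)
  merged <- merged[in_universe, , drop = FALSE]
  rownames(merged) <- NULL
  excl <- c(excl, seq_only_no_marker = n_off_marker)
  mat <- concordance_matrix(merged)
  category <- categorize_sites(merged, mode = "three")
  excl <- c(excl, unclassified = attr(category, "n_unclassified"))
  merged$category <- category
  list(
    matrix = mat,
    nrs = suppressWarnings(nrs(mat)),
    nrd = suppressWarnings(nrd(mat)),
    sites = merged,
    spectrum = allele_spectrum(merged, category),
    exclusions = excl
  )
}
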