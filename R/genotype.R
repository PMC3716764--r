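#' Genotype states
#'
#' Diploid genotype states used throughout the package. A site is "variant"
#' when its genotype is heterozygous or homozygous for the alternate allele.
#' `NO_CALL` is an explicitly emitted missing genotype (`./.` in a VCF) and is
#' distinct from a site being absent from a callset altogether (interpreted as
#' homozygous reference).
#'
#' @return Character vector of the four genotype states, in canonical order.
#' @export
genotype_states <- function() {
  c("HOM_REF", "HET", "HOM_ALT", "NO_CALL")
}

#' Is a genotype variant?
#'
#' @param g Character vector of genotype states.
#' @return Logical vector: `TRUE` for `HET` and `HOM_ALT`.
#' @export
is_variant <- function(g) {
  stopifnot(all(g %in% genotype_states()))
  g %in% c("HET", "HOM_ALT")
}

#' Is a genotype called?
#'
#' Called means any state other than `NO_CALL`; homozygous reference counts
#' as called.
#'
#' @param g Character vector of genotype states.
#' @return Logical vector.
#' @export
is_called <- function(g) {
  stopifnot(all(g %in% genotype_states()))
  g != "NO_CALL"
}

#' Classify a base substitution as transition or transversion
#'
#' Transitions are purine-purine (A<->G) and pyrimidine-pyrimidine (C<->T)
#' substitutions; all other substitutions are transversions.
#'
#' @param ref,alt Character vectors of single bases in `A`, `C`, `G`, `T`.
#' @return Logical vector: `TRUE` for transitions.
#' @export
is_transition <- function(ref, alt) {
  stopifnot(length(ref) == length(alt))
  purine <- c("A", "G")
  (ref %in% purine) == (alt %in% purine) & ref != alt
}

#' Transition/transversion ratio
#'
#' @param ref,alt Single-base allele vectors.
#' @return Ratio of transitions to transversions, or `NA_real_` when there
#'   are no transversions (undefined; never reported as 0 or a large number).
#' @export
tstv_ratio <- function(ref, alt) {
  if (length(ref) == 0L) return(NA_real_)
  ts <- sum(is_transition(ref, alt))
  tv <- length(ref) - ts
  if (tv == 0L) NA_real_ else ts / tv
}

#' Unordered reference/alternate allele combination
#'
#' Maps an ordered (ref, alt) base pair onto one of the six unordered
#' combinations `A/C`, `A/G`, `A/T`, `C/G`, `C/T`, `G/T`.
#'
#' @param ref,alt Character vectors of single bases in `A`, `C`, `G`, `T`;
#'   elementwise `ref != alt`.
#' @return Character vector of unordered combinations.
#' @export
allele_combination <- function(ref, alt) {
  bases <- c("A", "C", "G", "T")
  if (!all(ref %in% bases) || !all(alt %in% bases)) {
    stop("alleles must be single bases in {A,C,G,T}")
  }
  if (any(ref == alt)) stop("ref and alt must differ")
  ifelse(ref < alt, paste(ref, alt, sep = "/"), paste(alt, ref, sep = "/"))
}

#' The six unordered allele combinations
#' @return Character vector in canonical order.
#' @export
allele_combinations <- function() {
  c("A/C", "A/G", "A/T", "C/G", "C/T", "G/T")
}

# Reverse complement of single bases, vectorized.
complement_base <- function(b) {
  unname(c(A = "T", C = "G", G = "C", T = "A")[b])
}
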