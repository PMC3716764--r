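#' Number of reads needed for a target fold-coverage
#'
#' Solves the coverage equation `C = (N * L) / G` for N: the number of
#' single reads of length `L` needed to reach average coverage `C` over a
#' territory of `G` base pairs (here the total length of the capture
#' targets). Rounded up to a whole read.
#'
#' @param coverage Desired fold-coverage C (> 0). Vectorized.
#' @param span Territory size G in bp (> 0).
#' @param read_length Read length L in bp (> 0); 101 for the sequencing
#'   design this package emulates.
#' @return Integer read count(s) `ceiling(C * G / L)`.
#' @export
reads_for_coverage <- function(coverage, span, read_length = 101L) {
  stopifnot(all(coverage > 0), span > 0, read_length > 0)
  as.integer(ceiling(coverage * span / read_length))
}

#' Keep reads with at least 1 bp of target overlap
#'
#' @param reads data.frame with `read_id`, `chrom`, `start` (0-based),
#'   `end` (exclusive), `pair_id`.
#' @param targets Normalized target data.frame.
#' @return The retained subset of `reads` (row order preserved).
#' @export
filter_on_target <- function(reads, targets) {
  if (nrow(reads) == 0L) return(reads)
  q <- GenomicRanges::GRanges(reads$chrom,
                              IRanges::IRanges(reads$start + 1L,
                                               end = reads$end))
  keep <- IRanges::overlapsAny(q, targets_as_granges(targets),
                               minoverlap = 1L)
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Seeded bootstrap subsampling of reads
#'
#' Draws `B` replicate subsamples of `n` reads each, without replacement
#' within a replicate ("bootstrap" here is repeated subsampling of an
#' alignment, not with-replacement resampling). Replicate seeds are derived
#' deterministically from the master seed, so identical inputs and master
#' seed reproduce identical subsamples.
#'
#' @param n_reads Number of reads available.
#' @param n Subsample size per replicate; capped at `n_reads` with a warning.
#' @param replicates Number of replicates B.
#' @param master_seed Master seed.
#' @return List of B sorted integer index vectors into the read set.
#' @export
bootstrap_downsample <- function(n_reads, n, replicates, master_seed) {
  stopifnot(n_reads >= 0, replicates >= 1)
  if (n > n_reads) {
    warning("requested ", n, " reads but only ", n_reads,
            " available; capping")
    n <- n_reads
  }
  seeds <- derive_seeds(master_seed, replicates)
  lapply(seeds, function(s) {
    with_seed(s, sort(sample.int(n_reads, n)))
  })
}

#' Random subset of read pairs
#'
#' Uniform sample of `n_pairs` read pairs without replacement, both mates
#' kept together, original order preserved.
#'
#' @param total_pairs Number of pairs available.
#' @param n_pairs Number of pairs to keep (`<= total_pairs`).
#' @param seed Seed.
#' @return Sorted integer vector of selected pair indices.
#' @export
subset_read_pairs <- function(total_pairs, n_pairs, seed) {
  stopifnot(n_pairs <= total_pairs, n_pairs >= 0)
  if (n_pairs == 0L) return(integer(0))
  with_seed(seed, sort(sample.int(total_pairs, n_pairs)))
}

#' Depth-driven genotype recall model (synthetic data only)
#'
#' A minimal caller used to connect read depth to callable variants on
#' synthetic data, so the downsampling design can be exercised end-to-end.
#' A site is NO_CALL below the callability floor (default 5, mirroring the
#' hard filter's depth term); otherwise the alternate-allele read fraction
#' decides: HET within `[het_lo, het_hi]`, HOM_ALT above `het_hi`, HOM_REF
#' below `het_lo`. Never applied to real callsets.
#'
#' @param depth Integer read depth per site. Vectorized.
#' @param alt_reads Alternate-supporting read count per site (`<= depth`).
#' @param min_depth Callability floor (default 5).
#' @param het_lo,het_hi Heterozygous allele-fraction band (default 0.2/0.8).
#' @return Character vector of genotype states.
#' @export
recall_model <- function(depth, alt_reads, min_depth = 5L,
                         het_lo = 0.2, het_hi = 0.8) {
  stopifnot(length(depth) == length(alt_reads),
            all(alt_reads <= depth), all(alt_reads >= 0))
  frac <- ifelse(depth > 0, alt_reads / depth, 0)
  out <- rep("HOM_REF", length(depth))
  out[frac >= het_lo & frac <= het_hi] <- "HET"
  out[frac > het_hi] <- "HOM_ALT"
  out[depth < min_depth] <- "NO_CALL"
  out
}

#' Summarize per-replicate metrics
#'
#' Medians and interquartile ranges across bootstrap replicates, per
#' coverage level and metric.
#'
#' @param replicate_metrics data.frame with columns `coverage`, `replicate`,
#'   and one or more numeric metric columns (e.g. `n_snp`, `n_indel`,
#'   `nrs`, `nrd`).
#' @return data.frame with `coverage`, `metric`, `median`, `q1`, `q3`,
#'   `n_replicates`.
#' @export
summarize_replicates <- function(replicate_metrics) {
  metrics <- setdiff(names(replicate_metrics), c("coverage", "replicate"))
  sp <- split(replicate_metrics, replicate_metrics$coverage)
  out <- do.call(rbind, lapply(sp, function(d) {
    do.call(rbind, lapply(metrics, function(m) {
      x <- d[[m]]
      x <- x[!is.na(x)]
      q <- if (length(x) > 0) {
        stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      } else c(NA_real_, NA_real_, NA_real_)
      data.frame(coverage = d$coverage[1], metric = m,
                 median = q[2], q1 = q[1], q3 = q[3],
                 n_replicates = length(x), stringsAsFactors = FALSE)
    }))
  }))
  out <- out[order(out$metric, out$coverage), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bootstrap downsampling experiment on synthetic reads
#'
#' Runs the full downsampling design on a synthetic read set: for each
#' fold-coverage in the ladder, computes the required read count from the
#' coverage equation, draws B seeded subsamples of the on-target reads,
#' recomputes per-site depth and alternate support in each subsample, calls
#' genotypes with [recall_model()], and records per-replicate variant counts
#' and (when a comparison genotype vector is given) NRS/NRD against it.
#'
#' @param reads On-target read-placement data.frame (`read_id`, `chrom`,
#'   `start`, `end`, `pair_id`).
#' @param sites data.frame of true variant sites with `chrom`, `pos`,
#'   `vclass`, `g_true` (the latent genotype driving alternate-read draws).
#' @param targets Normalized target data.frame (defines the span G).
#' @param coverages Fold-coverage ladder, e.g. `c(20, 50, 80)`.
#' @param replicates Replicates per coverage level (default 100).
#' @param master_seed Master seed; all randomness derives from it.
#' @param read_length Read length L (default 101).
#' @param g_comp Optional comparison genotype per site; when given,
#'   per-replicate NRS/NRD of the recalled genotypes against it are
#'   recorded.
#' @return List with `replicate_metrics` (one row per coverage x replicate)
#'   and `summary` (from [summarize_replicates()]).
#' @export
downsample_experiment <- function(reads, sites, targets, coverages,
                                  replicates = 100L, master_seed = 1L,
                                  read_length = 101L, g_comp = NULL) {
  span <- target_span(targets)
  site_gr <- GenomicRanges::GRanges(sites$chrom,
                                    IRanges::IRanges(sites$pos, width = 1L))
  read_gr <- GenomicRanges::GRanges(reads$chrom,
                                    IRanges::IRanges(reads$start + 1L,
                                                     end = reads$end))
  hits <- GenomicRanges::findOverlaps(site_gr, read_gr)
  cover_site <- S4Vectors::queryHits(hits)
  cover_read <- S4Vectors::subjectHits(hits)
  p_alt <- c(HOM_REF = 0.01, HET = 0.5, HOM_ALT = 0.98)[sites$g_true]
  all_seeds <- derive_seeds(master_seed,
                            length(coverages) * (replicates + 1L))
  seeds_boot <- all_seeds[seq_along(coverages)]
  seeds_alt <- all_seeds[-seq_along(coverages)]
  si <- 0L
  rows <- vector("list", length(coverages) * replicates)
  for (ci in seq_along(coverages)) {
    n_need <- reads_for_coverage(coverages[ci], span, read_length)
    idx_list <- bootstrap_downsample(nrow(reads), n_need, replicates,
                                     seeds_boot[ci])
    for (r in seq_len(replicates)) {
      si <- si + 1L
      in_rep <- logical(nrow(reads))
      in_rep[idx_list[[r]]] <- TRUE
      depth <- tabulate(cover_site[in_rep[cover_read]], nbins = nrow(sites))
      alt <- with_seed(seeds_alt[si],
                       stats::rbinom(nrow(sites), depth, p_alt))
      g_call <- recall_model(depth, alt)
      row <- data.frame(coverage = coverages[ci], replicate = r,
                        n_snp = sum(is_variant(g_call) &
                                      sites$vclass == "SNP"),
                        n_indel = sum(is_variant(g_call) &
                                        sites$vclass == "INDEL"))
      if (!is.null(g_comp)) {
        lv <- genotype_states()
        mat <- table(factor(g_call, lv), factor(g_comp, lv))
        mat <- matrix(as.integer(mat), 4, 4, dimnames = list(lv, lv))
        row$nrs <- suppressWarnings(nrs(mat))
        row$nrd <- suppressWarnings(nrd(mat))
      }
      rows[[si]] <- row
    }
  }
  metrics <- do.call(rbind, rows)
  list(replicate_metrics = metrics, summary = summarize_replicates(metrics))
}
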