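#' GC percentage of a sequence
#'
#' `100 * (G + C) / (A + C + G + T)`; ambiguous bases (anything outside
#' `A`,`C`,`G`,`T`) are excluded from the denominator and counted in the
#' `n_ambiguous` attribute.
#'
#' @param sequence A character string or `Biostrings::DNAString`.
#' @return GC percentage in [0, 100] with attribute `n_ambiguous`;
#'   `NA_real_` when the sequence has no unambiguous bases.
#' @export
gc_percent <- function(sequence) {
  s <- Biostrings::DNAString(as.character(sequence))
  if (length(s) == 0L) stop("empty sequence")
  freq <- Biostrings::alphabetFrequency(s)
  acgt <- freq[c("A", "C", "G", "T")]
  n_amb <- length(s) - sum(acgt)
  gc <- if (sum(acgt) == 0L) NA_real_ else 100 * sum(acgt[c("C", "G")]) / sum(acgt)
  structure(gc, n_ambiguous = as.integer(n_amb))
}

#' GC percentage of target intervals against a reference
#'
#' @param targets Normalized target data.frame (0-based half-open).
#' @param reference Named `Biostrings::DNAStringSet` (or path to a FASTA
#'   file) covering the target chromosomes.
#' @return data.frame of targets with `gc_percent` and `n_ambiguous`.
#' @export
target_gc <- function(targets, reference) {
  if (is.character(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
  }
  out <- targets
  res <- lapply(seq_len(nrow(targets)), function(i) {
    chrom <- targets$chrom[i]
    if (!chrom %in% names(reference)) {
      stop("chromosome not in reference: ", chrom)
    }
    sub <- Biostrings::subseq(reference[[chrom]],
                              start = targets$start[i] + 1L,
                              end = targets$end[i])
    g <- gc_percent(sub)
    c(gc = as.numeric(g), amb = attr(g, "n_ambiguous"))
  })
  out$gc_percent <- vapply(res, `[[`, 1.0, "gc")
  out$n_ambiguous <- as.integer(vapply(res, `[[`, 1.0, "amb"))
  out
}

#' Sliding-window GC percentage
#'
#' Windows start at 0 and advance by `step`; by default 10 kbp windows with
#' a 5 kbp overlap. A trailing partial window is retained only when it
#' extends beyond the previous window's end and is at least `step / 2` long;
#' a partial window fully contained in the previous window's span is
#' dropped.
#'
#' @param sequence Character string or `DNAString`.
#' @param window Window width in bp (default 10000).
#' @param step Step between window starts in bp (default 5000).
#' @return data.frame with `start` (0-based), `end` (exclusive),
#'   `gc_percent`.
#' @export
windowed_gc <- function(sequence, window = 10000L, step = 5000L) {
  stopifnot(window > 0, step > 0, step <= window)
  s <- Biostrings::DNAString(as.character(sequence))
  len <- length(s)
  stopifnot(len > 0)
  starts <- seq(0L, max(0L, len - 1L), by = step)
  ends <- pmin(starts + window, len)
  width <- ends - starts
  keep <- width == window
  # trailing partial: must add new sequence and be >= step/2 long
  partial <- !keep & width >= step / 2
  if (any(partial)) {
    last_full_end <- if (any(keep)) max(ends[keep]) else 0L
    partial <- partial & ends > last_full_end
  }
  keep <- keep | partial
  starts <- starts[keep]; ends <- ends[keep]
  gc <- vapply(seq_along(starts), function(i) {
    as.numeric(gc_percent(Biostrings::subseq(s, starts[i] + 1L, ends[i])))
  }, 1.0)
  data.frame(start = starts, end = ends, gc_percent = gc)
}

#' Bin targets by GC quartiles
#'
#' Computes the first, median and third quartiles of the supplied GC
#' percentages (linear-interpolation quantiles) and assigns each value to
#' one of four bins: bin 1 = gc <= Q1, bin 2 = Q1 < gc <= Q2, bin 3 =
#' Q2 < gc <= Q3, bin 4 = gc > Q3. Edges are inclusive on the right.
#'
#' @param values Numeric vector of target GC percentages (>= 4 values).
#' @return List with `edges` (named Q1/Q2/Q3) and `bin` (integer 1..4 per
#'   value). Degenerate input (all values equal) puts everything in bin 1
#'   with a warning.
#' @export
quartile_bins <- function(values) {
  stopifnot(length(values) >= 4L, !any(is.na(values)))
  edges <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  names(edges) <- c("Q1", "Q2", "Q3")
  if (edges["Q1"] == edges["Q3"]) {
    warning("degenerate GC distribution: all targets in bin 1")
  }
  bin <- 1L + (values > edges["Q1"]) + (values > edges["Q2"]) +
    (values > edges["Q3"])
  list(edges = edges, bin = as.integer(bin))
}

#' Per-bin coverage summaries
#'
#' Five-number summary (min, Q1, median, Q3, max) of per-target median
#' coverage within each GC bin, per callset.
#'
#' @param bin Integer bin assignment per target (from [quartile_bins()]).
#' @param coverage data.frame with one row per target and per callset:
#'   columns `target_id`, `callset`, `median_coverage`; `target_id` indexes
#'   the same targets as `bin`.
#' @return data.frame with `bin`, `callset`, `n_targets`, `min`, `q1`,
#'   `median`, `q3`, `max`. Empty bins are absent.
#' @export
per_bin_coverage <- function(bin, coverage) {
  stopifnot(all(c("target_id", "callset", "median_coverage") %in%
                  names(coverage)))
  coverage$bin <- bin[coverage$target_id]
  sp <- split(coverage,
              list(bin = coverage$bin, callset = coverage$callset),
              drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    q <- stats::quantile(d$median_coverage, c(0, 0.25, 0.5, 0.75, 1),
                         type = 7, names = FALSE)
    data.frame(bin = d$bin[1], callset = d$callset[1], n_targets = nrow(d),
               min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$callset, out$bin), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-bin genotype concordance
#'
#' Assigns every merged variant site to the GC bin of its containing target
#' and computes NRS and NRD per bin and variant class. Variants outside all
#' targets are excluded and counted.
#'
#' @param bin Integer bin per target.
#' @param targets Normalized target data.frame (row order matches `bin`).
#' @param merged Merged-site table from [merge_callsets()].
#' @return data.frame with `bin`, `vclass`, `n_sites`, `nrs`, `nrd`;
#'   attribute `n_outside_targets` counts excluded variants.
#' @export
per_bin_concordance <- function(bin, targets, merged) {
  stopifnot(length(bin) == nrow(targets))
  q <- GenomicRanges::GRanges(merged$chrom,
                              IRanges::IRanges(merged$pos, width = 1L))
  hit <- GenomicRanges::findOverlaps(q, targets_as_granges(targets),
                                     select = "first")
  outside <- is.na(hit)
  merged <- merged[!outside, , drop = FALSE]
  site_bin <- bin[hit[!outside]]
  sp <- split(seq_len(nrow(merged)),
              list(bin = site_bin, vclass = merged$vclass), drop = TRUE)
  out <- do.call(rbind, lapply(names(sp), function(key) {
    idx <- sp[[key]]
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    mat <- concordance_matrix(merged[idx, , drop = FALSE])
    data.frame(bin = as.integer(parts[1]), vclass = parts[2],
               n_sites = length(idx),
               nrs = suppressWarnings(nrs(mat)),
               nrd = suppressWarnings(nrd(mat)),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$vclass, out$bin), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_outside_targets") <- sum(outside)
  out
}
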