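#' Read capture target intervals from a BED file
#'
#' Reads the first three columns of a BED file (0-based half-open
#' coordinates) and normalizes the result: intervals are sorted and
#' overlapping intervals merged. Abutting intervals (`[100,200)`,`[200,300)`)
#' are not merged, matching the half-open convention.
#'
#' @param path Path to a BED file with at least three columns.
#' @return data.frame with columns `chrom`, `start` (0-based), `end`
#'   (exclusive), sorted and non-overlapping.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 3L) stop("BED file must have >= 3 columns: ", path)
  df <- data.frame(chrom = as.character(raw[[1]]),
                   start = as.integer(raw[[2]]),
                   end = as.integer(raw[[3]]),
                   stringsAsFactors = FALSE)
  if (any(df$start >= df$end)) {
    stop("BED interval with start >= end in ", path)
  }
  normalize_intervals(df)
}

#' Normalize target intervals
#'
#' Sorts intervals and merges overlapping ones; idempotent. Coordinates stay
#' 0-based half-open.
#'
#' @param targets data.frame with `chrom`, `start`, `end`.
#' @return Normalized data.frame.
#' @export
normalize_intervals <- function(targets) {
  if (nrow(targets) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  stopifnot(all(targets$start < targets$end))
  gr <- targets_as_granges(targets)
  # min.gapwidth = 0 keeps abutting half-open intervals separate
  red <- GenomicRanges::reduce(GenomicRanges::sort(gr), min.gapwidth = 0L)
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red),
    stringsAsFactors = FALSE
  )
}

#' Write target intervals as BED3
#'
#' @param targets data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(targets, path) {
  utils::write.table(targets[, c("chrom", "start", "end")], path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Total span of target intervals in base pairs
#'
#' @param targets Normalized target data.frame.
#' @return Integer total length.
#' @export
target_span <- function(targets) {
  sum(targets$end - targets$start)
}
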