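# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so generators are pure functions of their
# seed and do not perturb user code.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Derive per-replicate seeds from a master seed
#'
#' Deterministically expands one master seed into `n` independent child seeds
#' (all below 2^31), so that every stochastic step of a multi-replicate design
#' is reproducible and individually re-runnable.
#'
#' @param master_seed Integer master seed.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`.
#' @export
derive_seeds <- function(master_seed, n) {
  stopifnot(n >= 0)
  if (n == 0L) return(integer(0))
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

# 1-based position -> is it inside any 0-based half-open target interval?
# `targets` is a data.frame(chrom, start, end). Vectorized over pos.
pos_in_targets <- function(chrom, pos, targets) {
  if (nrow(targets) == 0L) return(rep(FALSE, length(pos)))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
  s <- targets_as_granges(targets)
  IRanges::overlapsAny(q, s)
}

# data.frame(chrom, start [0-based], end [exclusive]) -> GRanges (1-based).
# The single owner of the BED off-by-one conversion.
targets_as_granges <- function(targets) {
  GenomicRanges::GRanges(
    targets$chrom,
    IRanges::IRanges(start = targets$start + 1L, end = targets$end)
  )
}
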