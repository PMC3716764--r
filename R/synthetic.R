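#' Joint genotype distribution from target concordance metrics
#'
#' Builds a 4x4 probability matrix over (evaluation genotype, comparison
#' genotype) — conditional on the site being materialized, i.e. at least one
#' side variant — whose implied NRS and NRD equal the requested values.
#' Construction: unit mass of shared (both-variant) sites, of which a
#' fraction `delta` (solved internally) are genotype-discordant HET/HOM_ALT
#' swaps; a missed mass (comparison variant, evaluation HOM_REF or NO_CALL)
#' sized so NRS comes out right, split `homref_frac_missed` : rest between
#' HOM_REF and NO_CALL; and a symmetric evaluation-only mass.
#'
#' Feasibility: the HOM_REF halves of the missed and evaluation-only masses
#' already contribute to NRD, so very low NRD targets require small
#' `homref_frac_*` values (most missed sites being explicit no-calls, the
#' pattern reported for the whole-exome data).
#'
#' @param nrs_target,nrd_target Target NRS and NRD in percent.
#' @param eval_only Evaluation-only mass relative to unit shared mass.
#' @param homref_frac_missed Fraction of missed sites that are HOM_REF
#'   (vs NO_CALL) in the evaluation callset.
#' @param homref_frac_evalonly Same for the comparison side of
#'   evaluation-only sites.
#' @param het_frac Fraction of heterozygous genotypes among concordant
#'   variant sites.
#' @return 4x4 probability matrix (rows = evaluation, cols = comparison)
#'   with attributes `nrs` and `nrd` (the implied analytic values).
#' @export
genotype_joint <- function(nrs_target, nrd_target, eval_only = 0.012,
                           homref_frac_missed = 0.1,
                           homref_frac_evalonly = 0.1,
                           het_frac = 0.65) {
  stopifnot(nrs_target > 0, nrs_target <= 100,
            nrd_target >= 0, nrd_target < 100)
  s <- 1
  m <- s * (100 - nrs_target) / nrs_target
  e <- eval_only
  fm <- homref_frac_missed; fe <- homref_frac_evalonly
  denom <- s + fm * m + fe * e
  delta <- (nrd_target / 100 * denom - fm * m - fe * e) / s
  if (delta < 0 || delta > 1) {
    stop("infeasible NRS/NRD combination: need 0 <= delta <= 1, got ",
         signif(delta, 4),
         "; lower homref_frac_missed/evalonly or raise nrd_target")
  }
  lv <- genotype_states()
  P <- matrix(0, 4, 4, dimnames = list(eval = lv, comp = lv))
  # shared, concordant
  P["HET", "HET"] <- s * (1 - delta) * het_frac
  P["HOM_ALT", "HOM_ALT"] <- s * (1 - delta) * (1 - het_frac)
  # shared, discordant (both variant)
  P["HET", "HOM_ALT"] <- s * delta / 2
  P["HOM_ALT", "HET"] <- s * delta / 2
  # missed by evaluation
  P["HOM_REF", "HET"] <- m * fm * het_frac
  P["HOM_REF", "HOM_ALT"] <- m * fm * (1 - het_frac)
  P["NO_CALL", "HET"] <- m * (1 - fm) * het_frac
  P["NO_CALL", "HOM_ALT"] <- m * (1 - fm) * (1 - het_frac)
  # evaluation-only
  P["HET", "HOM_REF"] <- e * fe * het_frac
  P["HOM_ALT", "HOM_REF"] <- e * fe * (1 - het_frac)
  P["HET", "NO_CALL"] <- e * (1 - fe) * het_frac
  P["HOM_ALT", "NO_CALL"] <- e * (1 - fe) * (1 - het_frac)
  P <- P / sum(P)
  im <- implied_metrics(P)
  stopifnot(abs(im$nrs - nrs_target) < 1e-9,
            abs(im$nrd - nrd_target) < 1e-9)
  attr(P, "nrs") <- im$nrs
  attr(P, "nrd") <- im$nrd
  P
}

#' Analytic NRS/NRD implied by a joint genotype distribution
#'
#' Applies the NRS and NRD definitions directly to the probability mass of
#' each (evaluation, comparison) genotype cell; this is the ground truth
#' the pipeline's estimates converge to on synthetic data.
#'
#' @param P 4x4 probability matrix (rows = evaluation, cols = comparison).
#' @return List with `nrs` and `nrd` in percent.
#' @export
implied_metrics <- function(P) {
  v <- c("HET", "HOM_ALT")
  called <- c("HOM_REF", "HET", "HOM_ALT")
  nrs_val <- 100 * sum(P[v, v]) / sum(P[, v])
  sub <- P[called, called]
  den <- sum(sub) - sub["HOM_REF", "HOM_REF"]
  nrd_val <- 100 * (sum(sub) - sum(diag(sub))) / den
  list(nrs = nrs_val, nrd = nrd_val)
}

#' Allele-combination spectrum for a target TsTv ratio
#'
#' Probability vector over the six unordered combinations placing
#' `tstv / (1 + tstv)` of the mass on the two transition combinations (A/G,
#' C/T, split evenly) and the rest evenly on the four transversions.
#'
#' @param tstv Target transition/transversion ratio.
#' @return Named probability vector over [allele_combinations()].
#' @export
spectrum_from_tstv <- function(tstv) {
  stopifnot(tstv >= 0)
  t_mass <- tstv / (1 + tstv)
  p <- stats::setNames(rep((1 - t_mass) / 4, 6), allele_combinations())
  p[c("A/G", "C/T")] <- t_mass / 2
  p
}

#' Synthetic study configuration
#'
#' Seeded generative parameters for every input the pipeline consumes. The
#' defaults emulate the whole-exome experiment at a scaled-down problem
#' size: a joint genotype distribution implying NRS 98.28% / NRD 0.63% for
#' SNPs (91.17% / 13.46% for INDELs), TsTv 2.85 for known and 1.81 for
#' novel SNPs, dbSNP fraction 0.986, mean coverage 92x (evaluation) / 80x
#' (comparison) with a GC coverage penalty above the third target-GC
#' quartile, 101 bp reads, and a Birdseed-like array model.
#'
#' @param seed Master seed; the configuration plus seed fully determines
#'   every generated artifact.
#' @param n_targets Number of capture targets.
#' @param target_length Min/max target length in bp.
#' @param gc_mean,gc_sd Programmed per-target GC%% distribution (normal,
#'   clipped to [20, 80]).
#' @param n_snv,n_indel Variant sites per class.
#' @param joint_snv,joint_indel 4x4 joint genotype distributions (see
#'   [genotype_joint()]).
#' @param tstv_known,tstv_novel Target TsTv ratios by dbSNP membership.
#' @param dbsnp_fraction Probability a site carries a dbSNP id.
#' @param category_spectra Optional named list of length-6 probability
#'   vectors overriding the allele spectrum per four-way category (used to
#'   program allele bias); default `NULL` = no bias, spectrum driven by
#'   `tstv_known`/`tstv_novel` alone.
#' @param filter_fail Named list of per-term failure-injection fractions
#'   (names from the filter terms, e.g. `LOW_DP`); default none — PASS
#'   annotations are drawn strictly inside the pass region with a safety
#'   margin so filter outcomes are deterministic.
#' @param mean_coverage_eval,mean_coverage_comp Mean fold-coverage per
#'   callset.
#' @param gc_penalty Multiplier on coverage for targets above the GC Q3
#'   (default 0.6; < 1 reproduces the high-GC coverage deficit).
#' @param high_gc_joint Optional joint distribution used for sites in
#'   targets above the GC Q3 (default: elevated discordance, NRS 96.5 /
#'   NRD 2.5), reproducing the high-GC concordance deficit. Set to
#'   `joint_snv` to disable.
#' @param read_length Read length in bp.
#' @param array_marker_fraction Fraction of SNP truth sites that carry an
#'   array marker.
#' @param array_n_homref On-target homozygous-reference markers.
#' @param array_n_offtarget Off-target markers (excluded by the target
#'   filter).
#' @param array_discordance Probability an array genotype is corrupted away
#'   from the comparison genotype.
#' @param array_nocall Array no-call probability.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(
    seed = 1L,
    n_targets = 200L,
    target_length = c(300L, 1500L),
    gc_mean = 48, gc_sd = 9,
    n_snv = 3000L, n_indel = 300L,
    joint_snv = genotype_joint(98.28, 0.63),
    joint_indel = genotype_joint(91.17, 13.46, eval_only = 0.06,
                                 homref_frac_missed = 0.5,
                                 homref_frac_evalonly = 0.5),
    tstv_known = 2.85, tstv_novel = 1.81,
    dbsnp_fraction = 0.986,
    category_spectra = NULL,
    filter_fail = list(),
    mean_coverage_eval = 92, mean_coverage_comp = 80,
    gc_penalty = 0.6,
    high_gc_joint = genotype_joint(96.5, 2.5),
    read_length = 101L,
    array_marker_fraction = 0.3,
    array_n_homref = 150L,
    array_n_offtarget = 200L,
    array_discordance = 0.013,
    array_nocall = 0.02) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_targets >= 0, cfg$target_length[1] <= cfg$target_length[2])
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate capture targets and their reference sequence
#'
#' Lays non-overlapping, sorted targets along one synthetic chromosome with
#' random inter-target gaps. Each target's base composition is constructed
#' to match its programmed GC%% exactly up to rounding (bases are counted
#' out, then shuffled), so realized GC is within half a percentage point of
#' programmed; gaps are filled at 40%% GC.
#'
#' @param config A `synthetic_config`.
#' @return List with `targets` (BED-style data.frame plus `gc_programmed`),
#'   `reference` (named `DNAStringSet` of one chromosome `chrS`), and
#'   `chrom`.
#' @export
generate_targets <- function(config) {
  cfg <- config
  chrom <- "chrS"
  if (cfg$n_targets == 0L) {
    return(list(
      targets = data.frame(chrom = character(0), start = integer(0),
                           end = integer(0), gc_programmed = numeric(0)),
      reference = Biostrings::DNAStringSet(stats::setNames("A", chrom)),
      chrom = chrom))
  }
  with_seed(cfg$seed, {
    lens <- sample(cfg$target_length[1]:cfg$target_length[2],
                   cfg$n_targets, replace = TRUE)
    gaps <- sample(200:2000, cfg$n_targets, replace = TRUE)
    gc <- pmin(80, pmax(20, stats::rnorm(cfg$n_targets, cfg$gc_mean,
                                         cfg$gc_sd)))
    starts <- cumsum(gaps) + c(0L, cumsum(lens))[seq_len(cfg$n_targets)]
    ends <- starts + lens
    total <- ends[cfg$n_targets] + 200L

    # gap background at 40% GC
    seq_chars <- sample(c("A", "C", "G", "T"), total, replace = TRUE,
                        prob = c(0.3, 0.2, 0.2, 0.3))
    comp_target <- function(len, gc_pct) {
      n_gc <- round(len * gc_pct / 100)
      bases <- c(sample(c("G", "C"), n_gc, replace = TRUE),
                 sample(c("A", "T"), len - n_gc, replace = TRUE))
      sample(bases)
    }
    for (i in seq_len(cfg$n_targets)) {
      seq_chars[(starts[i] + 1L):ends[i]] <- comp_target(lens[i], gc[i])
    }
    reference <- Biostrings::DNAStringSet(
      stats::setNames(paste(seq_chars, collapse = ""), chrom))
    targets <- data.frame(chrom = chrom, start = as.integer(starts),
                          end = as.integer(ends),
                          gc_programmed = gc, stringsAsFactors = FALSE)
    list(targets = targets, reference = reference, chrom = chrom)
  })
}

# Draw a pass-region annotation block for n records. Values keep a safety
# margin of at least one unit (0.01 for fractions) from every threshold so
# filter outcomes are deterministic.
draw_pass_annotations <- function(n, depth_lambda) {
  depth <- pmax(6L, stats::rpois(n, depth_lambda))
  mq0_cap <- floor(0.04 * depth)
  mq0 <- pmin(stats::rbinom(n, depth, 0.01), mq0_cap)
  data.frame(
    depth = depth, mq0 = as.integer(mq0),
    qual = stats::runif(n, 40, 2000),
    qd = stats::runif(n, 8, 25),
    hrun = sample(0:3, n, replace = TRUE),
    sb = stats::runif(n, -4, -1.1)  # clears both the SNP and INDEL SB terms
  )
}

# Overwrite one annotation so exactly the named term fails (just past its
# boundary), leaving the others in their pass region.
inject_term_failure <- function(ann, rows, term, vclass) {
  if (length(rows) == 0L) return(ann)
  if (term == "LOW_DP") {
    ann$depth[rows] <- sample(1:4, length(rows), replace = TRUE)
    ann$mq0[rows] <- 0L
  } else if (term == "LOW_QUAL") {
    lim <- if (vclass == "SNP") 30 else 10
    ann$qual[rows] <- stats::runif(length(rows), lim / 2, lim - 0.1)
  } else if (term == "LOW_QD") {
    ann$qd[rows] <- stats::runif(length(rows), 1, 4.9)
  } else if (term == "HRUN") {
    ann$hrun[rows] <- sample(6:9, length(rows), replace = TRUE)
  } else if (term == "STRAND_BIAS") {
    lim <- if (vclass == "SNP") -0.10 else -1.0
    ann$sb[rows] <- stats::runif(length(rows), lim, 0)
  } else if (term == "MQ0_FRACTION") {
    ann$mq0[rows] <- pmax(1L, ceiling(0.06 * ann$depth[rows]))
  } else stop("unknown term: ", term)
  ann
}

#' Generate a paired evaluation/comparison callset over targets
#'
#' Places SNV and INDEL sites uniformly within targets without collisions,
#' draws each site's (evaluation, comparison) genotype pair from the
#' configured joint distribution (sites in targets above the GC Q3 use
#' `high_gc_joint`), assigns dbSNP membership and alleles (the reference
#' base is the actual base of the generated reference; the alternate is
#' drawn from the TsTv-driven spectrum restricted to combinations containing
#' that base, or from the per-category override spectra when programmed),
#' and draws filter annotations. Sites homozygous-reference on one side emit
#' no record in that callset; explicit no-calls emit a `./.` record.
#'
#' @param config A `synthetic_config`.
#' @param targets_obj Result of [generate_targets()].
#' @return List with `eval_records`, `comp_records` (both
#'   `variant_records`), and `truth` — one row per site with every latent
#'   value (`g_eval`, `g_comp`, `category`, `known`, `high_gc` flag,
#'   `target_id`).
#' @export
generate_paired_callsets <- function(config, targets_obj) {
  cfg <- config
  targets <- targets_obj$targets
  stopifnot(nrow(targets) > 0)
  ref_seq <- targets_obj$reference[[targets_obj$chrom]]
  lv <- genotype_states()

  with_seed(cfg$seed + 1L, {
    # --- site positions: unique, uniform within targets -------------------
    lens <- targets$end - targets$start
    n_sites <- cfg$n_snv + cfg$n_indel
    if (n_sites > 0.5 * sum(lens)) {
      stop("too many sites for the configured target span")
    }
    offsets <- unlist(lapply(seq_len(nrow(targets)), function(i) {
      (targets$start[i] + 1L):targets$end[i]
    }))
    target_of <- rep(seq_len(nrow(targets)), lens)
    pick <- sample(length(offsets), n_sites)
    pos <- offsets[pick]
    target_id <- target_of[pick]
    vclass <- rep(c("SNP", "INDEL"), c(cfg$n_snv, cfg$n_indel))

    # --- GC bin of the containing target ---------------------------------
    gcb <- quartile_bins(targets$gc_programmed)
    high_gc <- gcb$bin[target_id] == 4L

    # --- genotype pairs ---------------------------------------------------
    draw_pairs <- function(P, n) {
      cells <- sample(16L, n, replace = TRUE, prob = as.vector(P))
      data.frame(g_eval = lv[(cells - 1L) %% 4L + 1L],
                 g_comp = lv[(cells - 1L) %/% 4L + 1L],
                 stringsAsFactors = FALSE)
    }
    g <- data.frame(g_eval = character(n_sites), g_comp = character(n_sites),
                    stringsAsFactors = FALSE)
    for (vc in c("SNP", "INDEL")) {
      base_joint <- if (vc == "SNP") cfg$joint_snv else cfg$joint_indel
      sel_lo <- vclass == vc & !high_gc
      sel_hi <- vclass == vc & high_gc
      g[sel_lo, ] <- draw_pairs(base_joint, sum(sel_lo))
      hi_joint <- if (vc == "SNP") cfg$high_gc_joint else base_joint
      if (any(sel_hi)) g[sel_hi, ] <- draw_pairs(hi_joint, sum(sel_hi))
    }

    # --- dbSNP membership and alleles -------------------------------------
    known <- stats::runif(n_sites) < cfg$dbsnp_fraction
    id <- ifelse(known, paste0("rs", sample.int(9e7, n_sites)), NA_character_)
    ref_base <- strsplit(as.character(
      Biostrings::extractAt(ref_seq, IRanges::IRanges(pos, width = 1L))
    ), "")
    ref_base <- unlist(lapply(ref_base, `[`, 1L))

    merged_like <- data.frame(g_eval = g$g_eval, g_comp = g$g_comp,
                              alt_eval = "X", alt_comp = "X",
                              vclass = vclass, stringsAsFactors = FALSE)
    category <- categorize_sites(merged_like, mode = "four")
    category[vclass == "INDEL"] <- NA_character_

    combos <- allele_combinations()
    combo_has <- sapply(combos, function(cb) {
      parts <- strsplit(cb, "/", fixed = TRUE)[[1]]
      stats::setNames(c("A", "C", "G", "T") %in% parts, c("A", "C", "G", "T"))
    })  # 4x6 logical: base x combo
    draw_alt <- function(rb, kn, cat) {
      p <- if (!is.null(cfg$category_spectra) && !is.na(cat) &&
               cat %in% names(cfg$category_spectra)) {
        cfg$category_spectra[[cat]]
      } else {
        spectrum_from_tstv(if (kn) cfg$tstv_known else cfg$tstv_novel)
      }
      w <- p * combo_has[rb, ]
      cb <- sample(combos, 1L, prob = w)
      parts <- strsplit(cb, "/", fixed = TRUE)[[1]]
      parts[parts != rb]
    }
    alt <- character(n_sites)
    is_snp <- vclass == "SNP"
    alt[is_snp] <- mapply(draw_alt, ref_base[is_snp], known[is_snp],
                          category[is_snp])
    # INDELs: 1-3 bp insertions or deletions anchored on the ref base
    n_ind <- sum(!is_snp)
    if (n_ind > 0L) {
      ins <- stats::runif(n_ind) < 0.5
      extra <- vapply(sample(1:3, n_ind, replace = TRUE), function(k) {
        paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
              collapse = "")
      }, "")
      r <- ref_base[!is_snp]
      ref_ind <- ifelse(ins, r, paste0(r, extra))
      alt_ind <- ifelse(ins, paste0(r, extra), r)
      ref_base[!is_snp] <- ref_ind
      alt[!is_snp] <- alt_ind
    }

    # --- assemble per-callset records -------------------------------------
    truth <- data.frame(
      chrom = targets_obj$chrom, pos = pos, vclass = vclass,
      ref = ref_base, alt = alt, known = known, id = id,
      g_eval = g$g_eval, g_comp = g$g_comp,
      category = category, high_gc = high_gc, target_id = target_id,
      stringsAsFactors = FALSE
    )
    truth <- truth[order(truth$pos), , drop = FALSE]
    rownames(truth) <- NULL

    build_side <- function(gcol) {
      gs <- truth[[gcol]]
      keep <- gs != "HOM_REF"
      d <- truth[keep, , drop = FALSE]
      ann <- draw_pass_annotations(nrow(d), depth_lambda = 60)
      for (term in names(cfg$filter_fail)) {
        frac <- cfg$filter_fail[[term]]
        for (vc in c("SNP", "INDEL")) {
          rows <- which(stats::runif(nrow(d)) < frac & d$vclass == vc)
          ann <- inject_term_failure(ann, rows, term, vclass = vc)
        }
      }
      variant_records(
        chrom = d$chrom, pos = d$pos, ref = d$ref, alt = d$alt,
        genotype = gs[keep], id = d$id, qual = ann$qual,
        depth = ann$depth, mq0 = ann$mq0, qd = ann$qd, hrun = ann$hrun,
        sb = ann$sb, vclass = d$vclass, filter = "."
      )
    }
    eval_records <- build_side("g_eval")
    comp_records <- build_side("g_comp")
    list(eval_records = eval_records, comp_records = comp_records,
         truth = truth)
  })
}

#' Generate per-target coverage, read placements, and per-site depths
#'
#' Expected per-target coverage is the callset mean times the GC penalty
#' (applied above the target-GC Q3) times lognormal target-to-target noise.
#' Read placements for the evaluation callset are laid uniformly across each
#' target at its realized coverage (plus off-target reads in the gaps);
#' per-site depth is Poisson at the containing target's realized coverage.
#'
#' @param config A `synthetic_config`.
#' @param targets_obj Result of [generate_targets()].
#' @param truth Truth table from [generate_paired_callsets()] (for per-site
#'   depth/alt draws); optional.
#' @return List with `coverage` (long data.frame: `target_id`, `callset`,
#'   `median_coverage`), `reads` (read-placement table for the evaluation
#'   callset), and `site_depth` (per-site `depth`, `alt_reads` for the
#'   evaluation callset; `NULL` without `truth`).
#' @export
generate_coverage_and_reads <- function(config, targets_obj, truth = NULL) {
  cfg <- config
  targets <- targets_obj$targets
  gcb <- quartile_bins(targets$gc_programmed)
  penalty <- ifelse(gcb$bin == 4L, cfg$gc_penalty, 1)
  with_seed(cfg$seed + 2L, {
    n_t <- nrow(targets)
    noise <- function() exp(stats::rnorm(n_t, 0, 0.15))
    cov_eval <- cfg$mean_coverage_eval * penalty * noise()
    cov_comp <- cfg$mean_coverage_comp * penalty * noise()
    coverage <- data.frame(
      target_id = rep(seq_len(n_t), 2L),
      callset = rep(c("eval", "comp"), each = n_t),
      median_coverage = c(cov_eval, cov_comp)
    )
    lens <- targets$end - targets$start
    n_reads_t <- stats::rpois(n_t, cov_eval * lens / cfg$read_length)
    starts <- unlist(lapply(seq_len(n_t), function(i) {
      if (n_reads_t[i] == 0L) return(integer(0))
      lo <- max(0L, targets$start[i] - cfg$read_length + 1L)
      sample(lo:(targets$end[i] - 1L), n_reads_t[i], replace = TRUE)
    }))
    # off-target reads in the inter-target gaps (dropped by the 1-bp rule)
    n_off <- round(0.1 * length(starts))
    chr_len <- length(targets_obj$reference[[targets_obj$chrom]])
    off_starts <- integer(0)
    if (n_off > 0L) {
      cand <- sample.int(chr_len - cfg$read_length, n_off * 3L,
                         replace = TRUE)
      q <- GenomicRanges::GRanges(
        targets_obj$chrom,
        IRanges::IRanges(cand + 1L, width = cfg$read_length))
      off <- !IRanges::overlapsAny(q, targets_as_granges(targets))
      off_starts <- cand[off][seq_len(min(n_off, sum(off)))]
    }
    all_starts <- c(starts, off_starts)
    ord <- sample(length(all_starts))  # shuffle on/off-target together
    all_starts <- all_starts[ord]
    reads <- data.frame(
      read_id = sprintf("r%07d", seq_along(all_starts)),
      chrom = targets_obj$chrom,
      start = as.integer(all_starts),
      end = as.integer(all_starts + cfg$read_length),
      pair_id = as.integer(ceiling(seq_along(all_starts) / 2))
    )
    site_depth <- NULL
    if (!is.null(truth)) {
      lam <- cov_eval[truth$target_id]
      depth <- stats::rpois(nrow(truth), lam)
      p_alt <- c(HOM_REF = 0.01, HET = 0.5, HOM_ALT = 0.98,
                 NO_CALL = 0.5)[truth$g_eval]
      site_depth <- data.frame(
        chrom = truth$chrom, pos = truth$pos,
        depth = depth,
        alt_reads = stats::rbinom(nrow(truth), depth, p_alt)
      )
    }
    list(coverage = coverage, reads = reads, site_depth = site_depth)
  })
}

#' Generate a SNP-array genotype table from the truth table
#'
#' Markers are placed on a configured fraction of the SNP truth sites (the
#' array genotype is the comparison genotype corrupted at the programmed
#' discordance and no-call rates), on additional on-target
#' homozygous-reference positions, and off-target. A/B alleles are the
#' site's ref/alt in random order, strand-flipped (reverse-complemented)
#' for a random half of the markers; Birdseed-like confidence scores are
#' drawn mostly below 0.05.
#'
#' @param config A `synthetic_config`.
#' @param targets_obj Result of [generate_targets()].
#' @param truth Truth table from [generate_paired_callsets()].
#' @return List with `array` (data.frame in [read_array_table()] layout),
#'   `ref_alleles` (marker reference frame: `chrom`, `pos`, `ref`, `alt`),
#'   and `truth_array` (latent array genotype per marker before A/B
#'   encoding).
#' @export
generate_array <- function(config, targets_obj, truth) {
  cfg <- config
  lv <- c("HOM_REF", "HET", "HOM_ALT")
  snp_truth <- truth[truth$vclass == "SNP", , drop = FALSE]
  with_seed(cfg$seed + 3L, {
    n_m <- round(cfg$array_marker_fraction * nrow(snp_truth))
    sites <- snp_truth[sample(nrow(snp_truth), n_m), , drop = FALSE]
    g_src <- sites$g_comp
    g_src[g_src == "NO_CALL"] <- "HOM_REF"  # array calls are genome-wide
    corrupt <- stats::runif(n_m) < cfg$array_discordance
    g_arr <- g_src
    if (any(corrupt)) {
      g_arr[corrupt] <- vapply(g_src[corrupt], function(gt) {
        sample(setdiff(lv, gt), 1L)
      }, "")
    }
    nocall <- stats::runif(n_m) < cfg$array_nocall
    df <- data.frame(chrom = sites$chrom, pos = sites$pos,
                     ref = sites$ref, alt = sites$alt,
                     g = g_arr, nocall = nocall, stringsAsFactors = FALSE)

    # on-target homozygous-reference markers at non-variant positions
    targets <- targets_obj$targets
    if (cfg$array_n_homref > 0L) {
      lens <- targets$end - targets$start
      offsets <- unlist(lapply(seq_len(nrow(targets)), function(i) {
        (targets$start[i] + 1L):targets$end[i]
      }))
      free <- setdiff(offsets, truth$pos)
      hp <- sample(free, min(cfg$array_n_homref, length(free)))
      rb <- substring(as.character(Biostrings::extractAt(
        targets_obj$reference[[targets_obj$chrom]],
        IRanges::IRanges(hp, width = 1L))), 1L, 1L)
      ab <- vapply(rb, function(b) sample(setdiff(c("A", "C", "G", "T"), b),
                                          1L), "")
      df <- rbind(df, data.frame(
        chrom = targets_obj$chrom, pos = hp, ref = rb, alt = ab,
        g = "HOM_REF", nocall = stats::runif(length(hp)) < cfg$array_nocall,
        stringsAsFactors = FALSE))
    }
    # off-target markers
    if (cfg$array_n_offtarget > 0L) {
      chr_len <- length(targets_obj$reference[[targets_obj$chrom]])
      cand <- sample.int(chr_len, cfg$array_n_offtarget * 3L)
      on <- pos_in_targets(targets_obj$chrom, cand, targets)
      op <- cand[!on][seq_len(min(cfg$array_n_offtarget, sum(!on)))]
      rb <- substring(as.character(Biostrings::extractAt(
        targets_obj$reference[[targets_obj$chrom]],
        IRanges::IRanges(op, width = 1L))), 1L, 1L)
      ab <- vapply(rb, function(b) sample(setdiff(c("A", "C", "G", "T"), b),
                                          1L), "")
      df <- rbind(df, data.frame(
        chrom = targets_obj$chrom, pos = op, ref = rb, alt = ab,
        g = sample(lv, length(op), replace = TRUE, prob = c(0.6, 0.3, 0.1)),
        nocall = FALSE, stringsAsFactors = FALSE))
    }
    df <- df[order(df$pos), , drop = FALSE]
    n <- nrow(df)
    # A/B encoding: random allele order, random strand flip
    a_is_ref <- stats::runif(n) < 0.5
    allele_a <- ifelse(a_is_ref, df$ref, df$alt)
    allele_b <- ifelse(a_is_ref, df$alt, df$ref)
    flip <- stats::runif(n) < 0.5
    allele_a[flip] <- complement_base(allele_a[flip])
    allele_b[flip] <- complement_base(allele_b[flip])
    call <- ifelse(df$nocall, "NO_CALL",
                   ifelse(df$g == "HET", "AB",
                          ifelse((df$g == "HOM_REF") == a_is_ref,
                                 "AA", "BB")))
    conf <- stats::rbeta(n, 1, 15) * 0.3
    array <- data.frame(
      marker = sprintf("SNP_A-%07d", seq_len(n)),
      chrom = df$chrom, pos = df$pos,
      allele_a = allele_a, allele_b = allele_b,
      call = call,
      confidence = round(conf, 4),
      stringsAsFactors = FALSE
    )
    list(array = array,
         ref_alleles = data.frame(chrom = df$chrom, pos = df$pos,
                                  ref = df$ref, alt = df$alt,
                                  stringsAsFactors = FALSE),
         truth_array = data.frame(chrom = df$chrom, pos = df$pos,
                                  g_array = ifelse(df$nocall, "NO_CALL",
                                                   df$g),
                                  stringsAsFactors = FALSE))
  })
}
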