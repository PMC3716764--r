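test_that("gc_percent counts unambiguous bases only", {
  expect_equal(as.numeric(gc_percent("GCGC")), 100)
  expect_equal(as.numeric(gc_percent("ATGC")), 50)
  g <- gc_percent("ATGCN")
  expect_equal(as.numeric(g), 50)
  expect_equal(attr(g, "n_ambiguous"), 1L)
  expect_true(is.na(gc_percent("NNNN")))
  expect_error(gc_percent(""), "empty")
  # base-counting oracle on random sequences
  set.seed(3)
  for (i in 1:100) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), sample(5:200, 1),
                      replace = TRUE, prob = c(.24, .24, .24, .24, .04)),
               collapse = "")
    ch <- strsplit(s, "")[[1]]
    n_gc <- sum(ch %in% c("G", "C")); n_ok <- sum(ch %in% c("A", "C", "G", "T"))
    expected <- if (n_ok == 0) NA_real_ else 100 * n_gc / n_ok
    expect_equal(as.numeric(gc_percent(s)), expected)
  }
})

test_that("windowed GC uses 10 kb windows stepping 5 kb", {
  s20 <- paste(rep("G", 20000), collapse = "")
  w <- windowed_gc(s20)
  expect_equal(nrow(w), 3L)
  expect_equal(w$start, c(0L, 5000L, 10000L))
  expect_equal(w$end - w$start, rep(10000L, 3))
  expect_equal(w$gc_percent, rep(100, 3))
  # window = sequence length -> single window equal to gc_percent
  s <- paste(rep(c("A", "G"), 500), collapse = "")
  w1 <- windowed_gc(s, window = 1000, step = 1000)
  expect_equal(nrow(w1), 1L)
  expect_equal(w1$gc_percent, as.numeric(gc_percent(s)))
  # a trailing partial that adds sequence and spans >= step/2 is kept
  s23 <- paste(rep("G", 23000), collapse = "")
  w23 <- windowed_gc(s23)
  expect_equal(utils::tail(w23$end, 1), 23000L)
  expect_error(windowed_gc(s, window = 0))
  expect_error(windowed_gc(s, window = 10, step = 20))
})

test_that("quartile binning uses interpolated quartiles with right-closed edges", {
  qb <- quartile_bins(c(10, 20, 30, 40))
  expect_equal(unname(qb$edges), c(17.5, 25, 32.5))
  expect_equal(qb$bin, 1:4)  # every bin non-empty
  # permutation invariance
  set.seed(9)
  v <- runif(40, 20, 80)
  perm <- sample(40)
  qb1 <- quartile_bins(v)
  qb2 <- quartile_bins(v[perm])
  expect_equal(qb2$bin, qb1$bin[perm])
  # a value exactly at an edge goes to the lower bin (right-closed)
  qv <- c(1, 2, 3, 4, 2)  # Q1 = 2
  expect_equal(quartile_bins(qv)$bin[5], 1L)
  expect_warning(qb0 <- quartile_bins(rep(5, 6)), "degenerate")
  expect_true(all(qb0$bin == 1L))
})

test_that("per-bin coverage summaries reduce to five-number summaries", {
  cov <- data.frame(target_id = 1:8, callset = "eval",
                    median_coverage = c(5, 10, 15, 20, 25, 30, 35, 40))
  one_bin <- per_bin_coverage(rep(1L, 8), cov)
  expect_equal(nrow(one_bin), 1L)
  q <- unname(quantile(cov$median_coverage, c(0, .25, .5, .75, 1)))
  expect_equal(unlist(one_bin[, c("min", "q1", "median", "q3", "max")],
                      use.names = FALSE), q)
  # empty bins are simply absent
  two <- per_bin_coverage(rep(c(1L, 4L), each = 4), cov)
  expect_equal(sort(two$bin), c(1L, 4L))
})

test_that("per-bin concordance assigns variants to containing targets", {
  targets <- data.frame(chrom = "c", start = c(0L, 100L),
                        end = c(50L, 200L))
  bin <- c(1L, 4L)
  m <- merged_from_pairs(c("HET", "HET", "HOM_REF", "HET"),
                         c("HET", "HOM_ALT", "HET", "HET"))
  m$chrom <- "c"
  m$pos <- c(10L, 150L, 160L, 999L)  # last site outside all targets
  pb <- per_bin_concordance(bin, targets, m)
  expect_equal(attr(pb, "n_outside_targets"), 1L)
  expect_equal(pb$n_sites[pb$bin == 1], 1L)
  expect_equal(pb$nrs[pb$bin == 1], 100)
  expect_equal(pb$nrd[pb$bin == 4], 100)  # both bin-4 sites discordant
  # boundary base: pos 50 is the last base of [0,50) -> bin 1
  m2 <- merged_from_pairs("HET", "HET"); m2$chrom <- "c"; m2$pos <- 50L
  pb2 <- per_bin_concordance(bin, targets, m2)
  expect_equal(pb2$bin, 1L)
  # all variants in one bin -> bin metrics equal global metrics
  m3 <- merged_from_pairs(c("HET", "NO_CALL"), c("HET", "HET"))
  m3$chrom <- "c"; m3$pos <- c(10L, 20L)
  pb3 <- per_bin_concordance(bin, targets, m3)
  mat <- concordance_matrix(m3)
  expect_equal(pb3$nrs, nrs(mat))
  expect_equal(pb3$nrd, nrd(mat))
})

test_that("synthetic GC penalty depresses bin-4 coverage and elevates bin-4 NRD", {
  cfg <- synthetic_config(seed = 5, n_targets = 80, n_snv = 4000,
                          n_indel = 0)
  tg <- generate_targets(cfg)
  gc <- target_gc(tg$targets, tg$reference)
  expect_true(all(abs(gc$gc_percent - tg$targets$gc_programmed) <= 2))
  qb <- quartile_bins(gc$gc_percent)
  cr <- generate_coverage_and_reads(cfg, tg)
  pbc <- per_bin_coverage(qb$bin, cr$coverage)
  med <- pbc$median[pbc$callset == "eval"][order(pbc$bin[pbc$callset == "eval"])]
  expect_equal(which.min(med), 4L)
  pc <- generate_paired_callsets(cfg, tg)
  fe <- filter_callset(pc$eval_records); fc <- filter_callset(pc$comp_records)
  m <- merge_callsets(fe$pass, fc$pass, tg$targets)
  pbn <- per_bin_concordance(qb$bin, tg$targets, m)
  snp <- pbn[pbn$vclass == "SNP", ]
  expect_equal(which.max(snp$nrd[order(snp$bin)]), 4L)
  # no variant double-counted across bins
  expect_equal(sum(snp$n_sites), nrow(m) - attr(pbn, "n_outside_targets"))
})
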