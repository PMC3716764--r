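test_that("the coverage equation yields ceil(C*G/L) reads", {
  expect_equal(reads_for_coverage(10, 1000, 100), 100L)
  # chr12 design: 200x over 3.87 Mbp of targets at 101 bp reads
  expect_equal(reads_for_coverage(200, 3870000, 101), 7663367L)
  # nondecreasing in C
  n <- reads_for_coverage(c(20, 50, 80, 100, 200, 300), 3870000, 101)
  expect_true(all(diff(n) > 0))
  expect_error(reads_for_coverage(-1, 1000, 100))
})

test_that("on-target filtering requires >= 1 bp overlap with half-open reads", {
  targets <- data.frame(chrom = "c", start = 100L, end = 200L)
  reads <- data.frame(read_id = c("a", "b", "c"), chrom = "c",
                      start = c(95L, 90L, 199L), end = c(105L, 100L, 299L),
                      pair_id = 1:3)
  kept <- filter_on_target(reads, targets)
  expect_equal(kept$read_id, c("a", "c"))  # [90,100) abuts, 0 overlap
  # brute-force sweep oracle on random reads
  set.seed(23)
  targets <- normalize_intervals(
    data.frame(chrom = "c", start = c(50L, 300L), end = c(150L, 420L)))
  covered <- rep(FALSE, 1000)
  for (i in seq_len(nrow(targets))) {
    covered[(targets$start[i] + 1):targets$end[i]] <- TRUE
  }
  starts <- sample(0:900, 300, replace = TRUE)
  reads <- data.frame(read_id = paste0("r", 1:300), chrom = "c",
                      start = starts, end = starts + 50L, pair_id = 1:300)
  expected <- vapply(seq_len(300), function(i) {
    any(covered[(reads$start[i] + 1):reads$end[i]])
  }, TRUE)
  expect_equal(filter_on_target(reads, targets)$read_id,
               reads$read_id[expected])
})

test_that("bootstrap subsampling is deterministic in the master seed", {
  a <- bootstrap_downsample(1000, 400, 5, master_seed = 77)
  b <- bootstrap_downsample(1000, 400, 5, master_seed = 77)
  expect_identical(a, b)
  c_ <- bootstrap_downsample(1000, 400, 5, master_seed = 78)
  expect_false(identical(a, c_))
  # replicates differ from each other but share the size
  expect_true(all(vapply(a, length, 1L) == 400L))
  expect_false(identical(a[[1]], a[[2]]))
  # n = all reads -> every replicate is the full set
  full <- bootstrap_downsample(50, 50, 3, master_seed = 1)
  expect_true(all(vapply(full, identical, TRUE, y = 1:50)))
  expect_warning(capped <- bootstrap_downsample(10, 20, 2, master_seed = 1),
                 "capping")
  expect_true(all(vapply(capped, length, 1L) == 10L))
})

test_that("read inclusion frequency at half-sampling is binomial", {
  B <- 1000L
  reps <- bootstrap_downsample(200, 100, B, master_seed = 5)
  freq <- tabulate(unlist(reps), nbins = 200) / B
  se <- sqrt(0.5 * 0.5 / B)
  expect_true(all(abs(freq - 0.5) < 4 * se))
  expect_lt(abs(mean(freq) - 0.5), 1e-12)
})

test_that("read-pair subsetting keeps mates together and samples uniformly", {
  expect_equal(subset_read_pairs(10, 10, seed = 1), 1:10)
  expect_equal(subset_read_pairs(10, 0, seed = 1), integer(0))
  expect_error(subset_read_pairs(10, 11, seed = 1))
  sel <- subset_read_pairs(100, 40, seed = 3)
  expect_equal(sel, sort(sel))
  expect_equal(anyDuplicated(sel), 0L)
  # uniformity: chi-square over 10,000 draws of 5 from 20
  set.seed(1)
  counts <- tabulate(unlist(lapply(1:2000, function(i) {
    subset_read_pairs(20, 5, seed = 10000 + i)
  })), nbins = 20)
  chi <- sum((counts - 500)^2 / 500)
  expect_lt(chi, qchisq(0.999, df = 19))
})

test_that("the recall model maps depth and allele fraction to genotypes", {
  expect_equal(recall_model(4, 2), "NO_CALL")   # below the callability floor
  expect_equal(recall_model(30, 15), "HET")
  expect_equal(recall_model(30, 29), "HOM_ALT")
  expect_equal(recall_model(30, 1), "HOM_REF")
  expect_equal(recall_model(c(30, 30), c(6, 24)), c("HET", "HET"))  # band edges
  expect_error(recall_model(10, 11))
})

test_that("replicate summaries are medians/IQRs matching a sort-based oracle", {
  d <- data.frame(coverage = rep(c(20, 50), each = 3), replicate = rep(1:3, 2),
                  n_snp = c(10, 20, 30, 40, 50, 60))
  s <- summarize_replicates(d)
  expect_equal(s$median, c(20, 50))
  one <- summarize_replicates(data.frame(coverage = 20, replicate = 1,
                                         n_snp = 42))
  expect_equal(one$median, 42)
  set.seed(8)
  d <- data.frame(coverage = 100, replicate = 1:50, x = rnorm(50))
  s <- summarize_replicates(d)
  xs <- sort(d$x)
  expect_equal(s$median, unname(quantile(xs, 0.5)))
  expect_true(s$median >= min(d$x) && s$median <= max(d$x))
})

test_that("variant recovery rises with coverage on synthetic reads", {
  cfg <- synthetic_config(seed = 13, n_targets = 40, n_snv = 600,
                          n_indel = 60, mean_coverage_eval = 100,
                          high_gc_joint = genotype_joint(98.28, 0.63))
  tg <- generate_targets(cfg)
  pc <- generate_paired_callsets(cfg, tg)
  cr <- generate_coverage_and_reads(cfg, tg, pc$truth)
  reads_on <- filter_on_target(cr$reads, tg$targets)
  sites <- pc$truth[pc$truth$g_comp != "NO_CALL",
                    c("chrom", "pos", "vclass")]
  sites$g_true <- pc$truth$g_comp[pc$truth$g_comp != "NO_CALL"]
  ds <- downsample_experiment(reads_on, sites, tg$targets,
                              coverages = c(5, 20, 80), replicates = 15,
                              master_seed = 99, g_comp = sites$g_true)
  s <- ds$summary
  n_snp <- s$median[s$metric == "n_snp"][order(s$coverage[s$metric == "n_snp"])]
  expect_true(all(diff(n_snp) >= 0))
  nrs_med <- s$median[s$metric == "nrs"][order(s$coverage[s$metric == "nrs"])]
  nrd_med <- s$median[s$metric == "nrd"][order(s$coverage[s$metric == "nrd"])]
  expect_true(all(diff(nrs_med) >= 0))
  expect_true(all(diff(nrd_med) <= 0))
  # determinism: identical master seeds reproduce identical replicates
  ds2 <- downsample_experiment(reads_on, sites, tg$targets,
                               coverages = c(5, 20, 80), replicates = 15,
                               master_seed = 99, g_comp = sites$g_true)
  expect_identical(ds$replicate_metrics, ds2$replicate_metrics)
})
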