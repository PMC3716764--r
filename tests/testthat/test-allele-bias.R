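test_that("four-way categorization assigns every merged SNP to one group", {
  m <- data.frame(
    chrom = "c", pos = 1:8, vclass = "SNP", ref = "A",
    alt_eval = c("G", "G", "G", NA, "G", "G", "T", NA),
    alt_comp = c("G", "G", NA, "G", "G", "G", "G", "G"),
    alt = "G",
    g_eval = c("HET", "HOM_ALT", "HET", "HOM_REF", "HET", "NO_CALL", "HET", "HOM_REF"),
    g_comp = c("HET", "HOM_ALT", "HOM_REF", "HET", "HOM_ALT", "HET", "HET", "HOM_ALT"),
    known = FALSE, stringsAsFactors = FALSE
  )
  cat4 <- categorize_sites(m, mode = "four")
  expect_equal(cat4, structure(
    c("CONCORDANT", "CONCORDANT", "EVAL_UNIQUE", "COMP_UNIQUE",
      "DISCORDANT", "COMP_UNIQUE", "DISCORDANT", "COMP_UNIQUE"),
    n_unclassified = 0L))
  # (NO_CALL, HET) is comparison-unique (NRS-contributing)
  expect_equal(cat4[6], "COMP_UNIQUE")
  # alt-allele disagreement with equal genotype is discordant
  expect_equal(cat4[7], "DISCORDANT")
  expect_false(any(is.na(cat4)))
})

test_that("three-way categorization matches NRS/NRD contribution", {
  m <- data.frame(
    chrom = "c", pos = 1:5, vclass = "SNP", ref = "A",
    alt_eval = c("G", NA, "G", "G", "G"),
    alt_comp = c("G", "G", "G", NA, NA),
    alt = "G",
    g_eval = c("HET", "NO_CALL", "HOM_ALT", "HET", "HET"),
    g_comp = c("HET", "HET", "HET", "HOM_REF", "NO_CALL"),
    known = FALSE, stringsAsFactors = FALSE
  )
  cat3 <- categorize_sites(m, mode = "three")
  expect_equal(unname(cat3[1:4]),
               c("CONCORDANT", "NRS_CONTRIBUTING", "NRD_CONTRIBUTING",
                 "NRD_CONTRIBUTING"))
  # array NO_CALL with a variant sequencing call fits no category
  expect_true(is.na(cat3[5]))
  expect_equal(attr(cat3, "n_unclassified"), 1L)
})

test_that("allele spectrum tabulates counts and within-category proportions", {
  ref <- c(rep("C", 4), rep("A", 2), rep("G", 2), "A", "A")
  alt <- c(rep("T", 4), rep("G", 2), rep("T", 2), "C", "T")
  m <- data.frame(chrom = "c", pos = 1:10, vclass = "SNP",
                  ref = ref, alt_eval = alt, alt_comp = alt, alt = alt,
                  g_eval = "HET", g_comp = "HET", known = FALSE,
                  stringsAsFactors = FALSE)
  sp <- allele_spectrum(m, rep("CONCORDANT", 10))
  expect_equal(unname(sp$counts["CONCORDANT", ]),
               c(1L, 2L, 1L, 0L, 4L, 2L))
  expect_equal(unname(sp$proportions["CONCORDANT", "C/T"]), 0.4)
  expect_equal(sum(sp$proportions["CONCORDANT", ]), 1)
  # randomized categories: proportions sum to 1 per non-empty category
  set.seed(5)
  cats <- sample(bias_categories("four"), 10, replace = TRUE)
  sp2 <- allele_spectrum(m, cats)
  sums <- rowSums(sp2$proportions)
  expect_true(all(abs(sums[!is.na(sums)] - 1) < 1e-12))
})

test_that("Fisher exact p-values match enumeration and an independent oracle", {
  expect_equal(fisher_exact_2x2(rbind(c(3, 1), c(1, 3))), 34 / 70,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(rbind(c(5, 5), c(5, 5))), 1)
  expect_warning(p0 <- fisher_exact_2x2(rbind(c(0, 0), c(3, 4))),
                 "zero margin")
  expect_equal(p0, 1)
  # 200 random tables with N <= 40 against stats::fisher.test
  set.seed(17)
  for (i in 1:200) {
    repeat {
      cells <- as.vector(stats::rmultinom(1, sample(4:40, 1), rep(0.25, 4)))
      tab <- matrix(cells, 2, 2)
      if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) break
    }
    expect_equal(fisher_exact_2x2(tab),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("pairwise bias tests adjust p-values and respect their bounds", {
  counts <- matrix(10L, nrow = 4, ncol = 6,
                   dimnames = list(bias_categories("four"),
                                   allele_combinations()))
  res <- pairwise_bias_test(counts)
  expect_equal(nrow(res), 36L)  # 6 combos x 6 category pairs
  expect_true(all(res$p_adj == 1))
  expect_false(any(res$significant))
  expect_true(all(res$p_adj >= res$p_raw))
  expect_true(all(res$p_adj <= 1))
  # two categories only: single pair, adjustment factor 1
  res2 <- pairwise_bias_test(counts[1:2, ], combination = "A/C")
  expect_equal(nrow(res2), 1L)
  expect_equal(res2$p_adj, res2$p_raw)
  expect_error(pairwise_bias_test(counts[1, , drop = FALSE]), ">= 2 categories")
})

test_that("a 3-fold inflated C/G proportion is detected at n = 2000 per category", {
  p <- spectrum_from_tstv(2.83)
  p_inflated <- p; p_inflated["C/G"] <- 3 * p_inflated["C/G"]
  p_inflated <- p_inflated / sum(p_inflated)
  set.seed(11)
  counts <- rbind(
    t(vapply(1:3, function(i) stats::rmultinom(1, 2000, p)[, 1],
             integer(6))),
    stats::rmultinom(1, 2000, p_inflated)[, 1]
  )
  dimnames(counts) <- list(bias_categories("four"), allele_combinations())
  res <- pairwise_bias_test(counts)
  cg <- res[res$combination == "C/G", ]
  involving <- cg$cat_a == "EVAL_UNIQUE" | cg$cat_b == "EVAL_UNIQUE"
  expect_true(all(cg$significant[involving]))
  # pairs among the three null categories stay quiet for C/G
  expect_false(any(cg$significant[!involving]))
})
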