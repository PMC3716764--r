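# six-site merge fixture covering the distinct merge cases
merge_fixture <- function() {
  ev <- bind_records(
    snp_record(100, "HET"),                       # shared, concordant
    snp_record(200, "HOM_ALT", ref = "C", alt = "T"),  # shared, discordant genotype
    snp_record(300, "HET", ref = "G", alt = "A"), # eval-only (absent in comp)
    snp_record(400, "NO_CALL"),                   # explicit no-call vs comp HET
    snp_record(600, "HET", ref = "T", alt = "G")  # shared but alt mismatch
  )
  cp <- bind_records(
    snp_record(100, "HET"),
    snp_record(200, "HET", ref = "C", alt = "T"),
    snp_record(400, "HET"),
    snp_record(500, "HOM_ALT", ref = "C", alt = "G", id = "rs9"),  # comp-only
    snp_record(600, "HET", ref = "T", alt = "C")
  )
  list(ev = ev, cp = cp)
}

test_that("merging keys sites, imputes HOM_REF for absent records, keeps both alts", {
  fx <- merge_fixture()
  m <- merge_callsets(fx$ev, fx$cp, toy_targets())
  expect_equal(nrow(m), 6L)
  byp <- function(p) m[m$pos == p, ]
  expect_equal(byp(100)$g_eval, "HET");     expect_equal(byp(100)$g_comp, "HET")
  expect_equal(byp(300)$g_comp, "HOM_REF")  # absent record -> HOM_REF
  expect_equal(byp(400)$g_eval, "NO_CALL")  # explicit ./. stays NO_CALL
  expect_equal(byp(500)$g_eval, "HOM_REF")
  expect_true(byp(500)$known)               # dbSNP id from either side
  expect_equal(byp(600)$alt_eval, "G")      # alt disagreement retained
  expect_equal(byp(600)$alt_comp, "C")
})

test_that("target restriction and reference conflicts are enforced", {
  fx <- merge_fixture()
  # narrow target excludes pos > 350
  m <- merge_callsets(fx$ev, fx$cp, toy_targets(end = 350L))
  expect_equal(sort(m$pos), c(100L, 200L, 300L))
  # ref mismatch at same key -> excluded and counted
  ev <- snp_record(100, "HET", ref = "A", alt = "G")
  cp <- snp_record(100, "HET", ref = "C", alt = "G")
  expect_warning(m2 <- merge_callsets(ev, cp), "mismatched reference")
  expect_equal(nrow(m2), 0L)
  expect_equal(attr(m2, "n_ref_conflicts"), 1L)
  # non-PASS input is rejected
  expect_error(merge_callsets(snp_record(1, "HET", filter = "LOW_DP"), cp),
               "PASS-only")
})

test_that("venn partition counts the fixture by hand and swaps under exchange", {
  fx <- merge_fixture()
  m <- merge_callsets(fx$ev, fx$cp, toy_targets())
  v <- venn_partition(m)
  # eval-only: pos 300; comp-only: 400 (NO_CALL vs HET), 500; intersection: 100,200,600
  expect_equal(v$n_eval_only, 1L)
  expect_equal(v$n_comp_only, 2L)
  expect_equal(v$n_intersection, 3L)
  m_swap <- merge_callsets(fx$cp, fx$ev, toy_targets())
  v_swap <- venn_partition(m_swap)
  expect_equal(v_swap$n_intersection, v$n_intersection)
  expect_equal(v_swap$n_eval_only, v$n_comp_only)
  expect_equal(v_swap$n_comp_only, v$n_eval_only)
  # identical callsets -> no unique fractions; disjoint -> empty intersection
  ident <- venn_partition(merge_callsets(fx$ev, fx$ev))
  expect_equal(ident$n_eval_only, 0L)
  expect_equal(ident$n_comp_only, 0L)
  disj <- venn_partition(merge_callsets(snp_record(1, "HET"),
                                        snp_record(2, "HET")))
  expect_equal(disj$n_intersection, 0L)
})

test_that("concordance matrix equals the hand tally on fixtures", {
  fx <- merge_fixture()
  m <- merge_callsets(fx$ev, fx$cp, toy_targets())
  mat <- concordance_matrix(m)
  expect_equal(sum(mat), nrow(m))
  expect_equal(mat["HOM_REF", "HOM_REF"], 0L)
  expect_equal(mat, oracle_matrix(m))
  expect_equal(sum(concordance_matrix(m[0, ])), 0L)
  ten <- merged_from_pairs(rep("HET", 10), rep("HET", 10))
  expect_equal(concordance_matrix(ten)["HET", "HET"], 10L)
})

test_that("NRS and NRD follow their definitions on constructed matrices", {
  # identical callsets
  ident <- concordance_matrix(merged_from_pairs(c("HET", "HOM_ALT"),
                                                c("HET", "HOM_ALT")))
  expect_equal(nrs(ident), 100)
  expect_equal(nrd(ident), 0)
  # 10 comp-variant sites, 4 missed -> NRS 60
  m <- merged_from_pairs(c(rep("HET", 6), rep("HOM_REF", 2), rep("NO_CALL", 2)),
                         rep("HET", 10))
  expect_equal(nrs(concordance_matrix(m)), 60)
  # NRD: (HET,HET)=8, (HET,HOM_ALT)=1, (HOM_REF,HET)=1 -> 2/10
  m <- merged_from_pairs(c(rep("HET", 9), "HOM_REF"),
                         c(rep("HET", 8), "HOM_ALT", "HET"))
  expect_equal(nrd(concordance_matrix(m)), 20)
  # all eligible discordant -> 100
  m <- merged_from_pairs(c("HET", "HOM_REF"), c("HOM_ALT", "HET"))
  expect_equal(nrd(concordance_matrix(m)), 100)
  # NO_CALL excluded from NRD but reduces NRS
  m <- merged_from_pairs(c("NO_CALL", "HET"), c("HET", "HET"))
  expect_equal(nrd(concordance_matrix(m)), 0)
  expect_equal(nrs(concordance_matrix(m)), 50)
  # undefined denominators are NA with a warning, never 0 or 100
  empty <- concordance_matrix(merged_from_pairs(character(0), character(0)))
  expect_warning(expect_true(is.na(nrs(empty))), "undefined")
  expect_warning(expect_true(is.na(nrd(empty))), "undefined")
  only_eval <- concordance_matrix(merged_from_pairs("HET", "NO_CALL"))
  expect_warning(expect_true(is.na(nrs(only_eval))), "undefined")
})

test_that("matrix metrics agree with the brute-force re-scan oracle", {
  pairs <- valid_genotype_pairs()
  # exhaustive 1-site tables
  for (i in seq_len(nrow(pairs))) {
    m <- merged_from_pairs(pairs$g_eval[i], pairs$g_comp[i])
    mat <- concordance_matrix(m)
    expect_identical(mat, oracle_matrix(m))
    expect_identical(suppressWarnings(nrs(mat)), oracle_nrs(m))
    expect_identical(suppressWarnings(nrd(mat)), oracle_nrd(m))
  }
  # exhaustive 2-site tables
  for (i in seq_len(nrow(pairs))) {
    for (j in seq_len(nrow(pairs))) {
      m <- merged_from_pairs(c(pairs$g_eval[i], pairs$g_eval[j]),
                             c(pairs$g_comp[i], pairs$g_comp[j]))
      mat <- concordance_matrix(m)
      expect_identical(suppressWarnings(nrs(mat)), oracle_nrs(m))
      expect_identical(suppressWarnings(nrd(mat)), oracle_nrd(m))
    }
  }
  # random tables up to 6 sites and a handful of 1,000-site fixtures
  set.seed(2024)
  for (rep in 1:300) {
    n <- sample(1:6, 1)
    idx <- sample(nrow(pairs), n, replace = TRUE)
    m <- merged_from_pairs(pairs$g_eval[idx], pairs$g_comp[idx])
    mat <- concordance_matrix(m)
    expect_identical(suppressWarnings(nrs(mat)), oracle_nrs(m))
    expect_identical(suppressWarnings(nrd(mat)), oracle_nrd(m))
    v <- venn_partition(m)
    ov <- oracle_venn(m)
    expect_equal(c(v$n_eval_only, v$n_comp_only, v$n_intersection),
                 unname(ov))
  }
})

test_that("callset summaries compute counts, dbSNP percent and TsTv by class", {
  recs <- bind_records(
    snp_record(1:29, "HET", ref = "A", alt = "G", id = paste0("rs", 1:29)),
    snp_record(31:42, "HET", ref = "A", alt = "C")
  )
  s <- callset_summary(recs)
  expect_equal(s$n_variants, 41L)
  expect_equal(s$dbsnp_percent, 100 * 29 / 41)
  expect_equal(s$tstv_overall, 29 / 12)
  expect_true(is.na(s$tstv_known))  # known sites have no transversions
  expect_true(is.na(s$tstv_novel) || s$tstv_novel == 0)  # novel all transversions
  all_known <- snp_record(1:5, "HET", id = paste0("rs", 1:5))
  expect_equal(callset_summary(all_known)$dbsnp_percent, 100)
  # 20-SNP hand-labelled fixture: 12 known Ts, 3 known Tv, 4 novel Ts, 1 novel Tv
  recs <- bind_records(
    snp_record(1:12, "HET", ref = "C", alt = "T", id = paste0("rs", 1:12)),
    snp_record(13:15, "HET", ref = "C", alt = "G", id = paste0("rs", 13:15)),
    snp_record(16:19, "HET", ref = "A", alt = "G"),
    snp_record(20, "HET", ref = "A", alt = "T")
  )
  s <- callset_summary(recs)
  expect_equal(s$n_variants, 20L)
  expect_equal(s$dbsnp_percent, 75)
  expect_equal(s$tstv_overall, 16 / 4)
  expect_equal(s$tstv_known, 12 / 3)
  expect_equal(s$tstv_novel, 4 / 1)
})

test_that("estimated NRS/NRD converge to the analytic values of the joint", {
  cfg <- synthetic_config(seed = 31, n_targets = 150, n_snv = 8000,
                          n_indel = 0,
                          high_gc_joint = genotype_joint(98.28, 0.63))
  tg <- generate_targets(cfg)
  pc <- generate_paired_callsets(cfg, tg)
  fe <- filter_callset(pc$eval_records)
  fc <- filter_callset(pc$comp_records)
  m <- merge_callsets(fe$pass, fc$pass, tg$targets)
  mat <- concordance_matrix(m)
  truth_nrs <- attr(cfg$joint_snv, "nrs")
  truth_nrd <- attr(cfg$joint_snv, "nrd")
  n_comp <- sum(mat[, c("HET", "HOM_ALT")])
  se_nrs <- 100 * sqrt(truth_nrs / 100 * (1 - truth_nrs / 100) / n_comp)
  expect_lt(abs(nrs(mat) - truth_nrs), 3 * se_nrs)
  called <- mat[1:3, 1:3]; n_eligible <- sum(called) - called[1, 1]
  se_nrd <- 100 * sqrt(truth_nrd / 100 * (1 - truth_nrd / 100) / n_eligible)
  expect_lt(abs(nrd(mat) - truth_nrd), 3 * se_nrd)
})
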