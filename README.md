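# wgaconcord

Evaluation of variant callsets derived from whole-genome-amplified (WGA)
DNA against callsets from unamplified genomic DNA of the same individual.

Targeted resequencing needs micrograms of input DNA; archived or
non-invasively collected samples often cannot supply that, and whole-genome
amplification is the standard rescue. Before trusting WGA-derived variant
calls, one wants to know how much they deviate from calls made on genomic
DNA. This package implements the complete paired-callset evaluation for
that question, restricted to capture targets: post-call hard filtering of
SNP and INDEL calls, site-level Venn analysis with TsTv/dbSNP summaries,
genotype concordance, allele-bias testing, GC-binned coverage and
concordance, bootstrap read downsampling, and validation against SNP-array
genotypes. A seeded synthetic-data module generates every input with
programmed statistical structure, so the whole pipeline can be exercised
against a known ground truth. It is aimed at sequencing-core and
methods-evaluation work, not at variant calling itself (alignment and the
caller are upstream and out of scope).

## The core metrics

All genotype comparisons reduce to a 4×4 concordance matrix of
(evaluation genotype × comparison genotype) counts over merged sites, with
states HOM_REF, HET, HOM_ALT, NO_CALL. From it:

* **NRS (non-reference sensitivity)** — the percentage of
  comparison-callset variant sites also called variant in the evaluation
  callset: `NRS = 100 · #{both variant} / #{comparison variant}`. Sites
  hom-ref or no-call in the evaluation callset reduce it.
* **NRD (non-reference discrepancy)** — the percentage of discordant
  genotypes among sites genotyped in both callsets, excluding concordant
  hom-ref sites: `NRD = 100 · #{called both, differing} / (#{called both} −
  #{both hom-ref})`. No-calls are excluded from both sides of the ratio.

Hard filters are fixed boolean expressions over site annotations — for
SNPs `MQ0/DP > 0.05 | DP < 5 | QUAL < 30 | QD < 5 | HRun > 5 | SB ≥ −0.10`,
for INDELs `MQ0/DP > 0.05 | SB ≥ −1.0 | QUAL < 10` — and only PASS records
enter any comparison. Allele bias is tested per ref/alt base combination
with pairwise Fisher exact tests (hypergeometric enumeration) under
Bonferroni correction. See the vignette
(`vignettes/paired-callset-concordance.Rmd`) for the full method account.

## Worked example

Generate a small paired study, filter both callsets, merge over targets,
and compute concordance:

```r
library(wgaconcord)

cfg <- synthetic_config(seed = 7, n_targets = 60, n_snv = 1500, n_indel = 150)
tg  <- generate_targets(cfg)
pc  <- generate_paired_callsets(cfg, tg)
ev  <- filter_callset(pc$eval_records)$pass
cp  <- filter_callset(pc$comp_records)$pass
merged <- merge_callsets(ev, cp, tg$targets)
rep <- report_concordance(merged, vclass = "SNP")
sprintf("NRS: %.2f%%  NRD: %.2f%%", rep$nrs, rep$nrd)
rep$matrix
```

prints

```
[1] "NRS: 98.31%  NRD: 1.23%"
         comp
eval      HOM_REF HET HOM_ALT NO_CALL
  HOM_REF       0   5       0       0
  HET           2 925       5      11
  HOM_ALT       1   5     523       3
  NO_CALL       0  14       6       0
```

Reading the matrix: 925 + 523 sites agree as HET/HOM_ALT; the 14 + 6
no-calls and 5 + 0 hom-ref calls in the evaluation callset are the NRS
losses (comparison-variant sites the evaluation callset missed); the
off-diagonal called cells drive NRD. The generator's defaults program an
NRS of 98.28% with extra discordance in high-GC targets, and the measured
98.31% recovers it within sampling error. `callset_summary()` adds the
Table-style per-callset metrics (counts, dbSNP %, TsTv overall/novel/known).

## The analysis pipeline

`analysis/` holds numbered drivers that run the full study on generated
data and write plain TSV/JSON tables under `results/`:

```sh
Rscript analysis/01_simulate.R         # targets, reference, paired VCFs, reads, array
Rscript analysis/02_filter.R           # hard filters + per-term failure summary
Rscript analysis/03_concordance.R      # merge, matrix, NRS/NRD, Venn, summaries
Rscript analysis/04_allele_bias.R      # spectra + pairwise Fisher tests
Rscript analysis/05_gc_coverage.R      # GC bins, coverage and concordance by bin
Rscript analysis/06_downsampling.R     # bootstrap coverage ladder, replicate medians
Rscript analysis/07_array_validation.R # SNP-array concordance, 3-way spectra
```

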