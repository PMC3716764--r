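---
title: "Evaluating WGA-derived variant callsets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating WGA-derived variant callsets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgaconcord)
```

## The problem

Whole-genome amplification (WGA) turns nanograms of archived DNA into the
micrograms that hybridization capture and sequencing library preparation
require. The question this package addresses is whether variant calls made
from WGA DNA can stand in for calls made from unamplified genomic DNA of the
same individual. The evaluation design is a paired comparison of two
single-sample callsets over capture targets: the WGA calls play the role of
the *evaluation* callset and the genomic calls the *comparison* callset.
Everything downstream — hard filtering, site-level Venn analysis, genotype
concordance, allele-bias testing, coverage structure, downsampling, and
SNP-array validation — operates on that pair.

## Genotype concordance: NRS and NRD

Both metrics are computed from a 4×4 concordance matrix of (evaluation
genotype × comparison genotype) counts over merged sites, with genotype
states HOM_REF, HET, HOM_ALT and NO_CALL.

**Non-reference sensitivity (NRS)** is the percentage of comparison-callset
variant sites (HET or HOM_ALT) that are also called variant in the
evaluation callset:

$$\mathrm{NRS} = 100 \times
  \frac{\#\{\text{both variant}\}}{\#\{\text{comparison variant}\}}.$$

Sites homozygous reference *or* no-call in the evaluation callset reduce
NRS; the two states are tracked separately because they behave differently
under NRD.

**Non-reference discrepancy (NRD)** is the percentage of discordant
genotypes among sites genotyped in both callsets, excluding concordant
homozygous-reference sites:

$$\mathrm{NRD} = 100 \times
  \frac{\#\{\text{called in both, } g_e \ne g_c\}}
       {\#\{\text{called in both}\} - \#\{\text{both HOM\_REF}\}}.$$

A NO_CALL on either side removes the site from both the numerator and the
denominator of NRD.

### Merge semantics

The merged table is keyed by (chromosome, position, variant class), after
both callsets are restricted to PASS records inside the capture targets.
Two deliberate conventions:

* **A site absent from one callset is homozygous reference there.** The
  caller walked that territory and emitted nothing, which is an implicit
  reference call. An explicitly emitted `./.` record is NO_CALL instead.
  Both reduce NRS, but only NO_CALL is excluded from NRD. This distinction
  reconciles "homozygous reference or no calls" being two different fates
  for a missed site.
* **SNP sites match on position, not on the alternate allele.** The Venn
  analysis is a coordinate intersection; when the two callsets disagree on
  the alternate allele at a shared position, both alleles are retained and
  the site counts as a genotype discordance in the categorization. INDELs
  are matched on the exact (position, ref, alt) triple — no left
  normalization is applied, which is conservative and flagged in reports.
* Sites with a reference-allele mismatch at a shared key indicate
  inconsistent inputs; they are excluded and counted rather than guessed
  at.
* Ratios with empty denominators (NRS with no comparison variants, NRD
  with no doubly-called sites, TsTv with no transversions) are reported as
  a typed missing value, never silently as 0 or 100.

## Hard filters

Post-call filtering uses fixed boolean expressions over the per-site
annotations. A SNP fails when any of

```
MQ0/DP > 0.05  |  DP < 5  |  QUAL < 30.0  |  QD < 5.0  |  HRun > 5.0  |  SB >= -0.10
```

holds, and an INDEL when any of

```
MQ0/DP > 0.05  |  SB >= -1.0  |  QUAL < 10
```

holds. Inequalities are implemented exactly as written — strict `<`/`>`,
inclusive `>=` on strand bias — because boundary behavior is observable (a
record with SB exactly −0.10 fails). Two edge rules: a record with depth 0
fails outright with the depth term and the MQ0 fraction is skipped (division
guard); a record missing an annotation skips that term rather than failing
it, with a counter, mirroring permissive engine behavior. Thresholds are
configurable (`filter_thresholds()`), with these values as defaults.

## Callset summaries and Venn partitions

Per callset and per partition (evaluation-only, comparison-only,
intersection) the package reports variant counts, the dbSNP fraction
(proportion of records carrying a marker identifier — membership is encoded
purely by a non-absent ID, no external database lookup), and
transition/transversion ratios overall and split by dbSNP membership.
Transitions are A↔G and C↔T. Because true variant sets are
transition-enriched while errors are not, a depressed TsTv in a partition
(typically the unique fractions) flags likely false positives.

## Allele-bias testing

Merged SNP sites fall into four categories: concordant, comparison-unique
(NRS-contributing), discordant (NRD-contributing), and evaluation-unique.
Within each category the six unordered ref/alt base combinations (A/C, A/G,
A/T, C/G, C/T, G/T) are tallied. For each combination, every pair of
categories is tested with a two-sided Fisher exact test on the 2×2 table
(combination count vs all-other count) × (category A vs category B), with
Bonferroni correction at α = 0.05.

The Fisher p-value is computed by hypergeometric enumeration: the sum of
point probabilities of all tables with the observed margins whose
probability does not exceed the observed table's, with a relative tolerance
of 10⁻⁷ on that comparison to guard floating-point ties. Two scopes for the
Bonferroni factor are exposed: per combination (×the number of category
pairs, the default, matching a pairwise procedure applied in succession to
each combination) and across the whole analysis (×pairs×combinations).
The first controls the familywise error within each combination; only the
second controls it across the full 36-test analysis, which is the property
the package's type-I simulations check.

A three-category mode (concordant / NRS-contributing / NRD-contributing)
serves the array-validation comparison, where an evaluation-unique category
is not meaningful. A site where the array is NO_CALL but the sequencing
call is variant fits none of the three categories and is excluded with a
count.

## GC structure

Target GC% is `100·(G+C)/(A+C+G+T)` with ambiguous bases excluded from the
denominator. Targets are binned by the first, second and third quartiles of
target GC%, computed with linear-interpolation quantiles (the common
default; the choice is recorded because bin membership near an edge depends
on it). Edges are right-closed: bin 4 is strictly above Q3, matching the
"GC% greater than Q3" reading. Per-bin outputs are five-number summaries of
median target coverage and NRS/NRD per variant class, with each variant
assigned to the bin of its containing (half-open) target.

Whole-sequence GC is also computed in 10 kbp windows stepping 5 kbp. A
trailing partial window is kept only when it extends beyond the previous
window's end and is at least half a step long; a partial fully contained in
the previous window's span adds no new sequence and is dropped, so a 20 kbp
sequence yields exactly three full windows.

## Downsampling design

The read count needed for a fold-coverage C over a target span of G bp with
reads of length L is `N = ceil(C·G/L)`; L counts single reads (101 bp in
the emulated design), not pairs. Reads enter the pool only with ≥ 1 bp of
target overlap (half-open intervals: a read ending exactly where a target
starts does not overlap). Each of B replicates draws N reads *without*
replacement — "bootstrap" here means repeated subsampling of an alignment,
not with-replacement resampling — using per-replicate seeds derived
deterministically from one master seed, so identical inputs and master seed
reproduce identical subsamples byte for byte. Replicate metrics are
summarized by medians and interquartile ranges.

To connect depth to callable variants without an external caller, a
minimal recall model is applied to synthetic data only: a site is NO_CALL
below 5 reads (mirroring the filter's depth floor), otherwise the
alternate-read fraction decides HOM_REF (< 0.2), HET (0.2–0.8) or HOM_ALT
(> 0.8). It is a deliberate caricature — no base qualities, no genotype
likelihoods — sufficient to reproduce the qualitative coverage ladder
(variant counts nondecreasing, NRS nondecreasing and NRD nonincreasing in
coverage) and never applied to real callsets.

## SNP-array validation

Array markers enter validation when they overlap a capture target and pass
the confidence threshold. Birdseed confidence scores are better when
*lower*, so the default keeps `confidence <= 0.05`; the opposite direction
is exposed as an argument because the phrase "a confidence score of at
least 0.05" admits both readings. Marker A/B alleles are resolved against
the site's ref/alt directly or by reverse complement; A/T and C/G markers
are complement-ambiguous and excluded by default rather than
strand-guessed — a silent wrong guess would masquerade as exactly the kind
of allele bias the analysis is looking for. The validation universe is the
retained marker set: sequencing calls at positions the array does not assay
are out of scope and counted, and the array plays the comparison role in
the concordance engine.

## The synthetic generator

Every pipeline input can be generated with programmed statistical
structure, so each stage has a ground truth to recover:

* **Targets and reference.** Non-overlapping sorted targets along one
  synthetic chromosome; each target's base composition is constructed by
  counting out the programmed number of G/C bases and shuffling, so
  realized GC is within rounding of programmed (the generator promises
  2 percentage points). Gaps are filled at 40% GC.
* **Paired callsets.** Each site's (evaluation, comparison) genotype pair
  is drawn from a 4×4 joint distribution. `genotype_joint()` constructs
  that distribution from target NRS/NRD values plus three shape
  parameters: the evaluation-only mass, the HOM_REF-vs-NO_CALL split of
  missed sites, and the heterozygous fraction. The implied metrics are
  exact by construction (`implied_metrics()` recomputes them analytically),
  and low NRD targets are only feasible when most missed sites are
  explicit no-calls — the configuration reported for whole-exome data.
  Defaults emulate the whole-exome experiment: SNP NRS 98.28 / NRD 0.63,
  INDEL 91.17 / 13.46, TsTv 2.85 known / 1.81 novel, dbSNP fraction 0.986.
* **Alleles.** The reference base is the actual base of the generated
  sequence; the alternate is drawn from a TsTv-driven spectrum restricted
  to combinations containing that base (this restriction mildly distorts
  the realized spectrum, which is why TsTv assertions in the tests carry
  tolerances). Per-category spectrum overrides allow programming allele
  bias.
* **Annotations.** PASS records draw every annotation strictly inside the
  pass region with a margin of at least one unit (0.01 for fractions), so
  filter outcomes are deterministic; failure injection places a chosen
  fraction of records just past a chosen term's boundary. The default
  injects nothing, keeping concordance parameter-recovery conditions
  exactly the programmed joint distribution; the filtering driver script
  opts into nonzero rates. When records are filtered away, measured NRS
  falls below the programmed value by roughly the per-side failure rate —
  filtering converts shared sites into missed ones — which is the expected
  behavior, not an estimator bias.
* **Coverage and reads.** Expected target coverage is the callset mean
  times a GC penalty (0.6 by default, applied above the target-GC Q3)
  times lognormal noise; reads are laid uniformly at the realized
  coverage, with 10% off-target reads to exercise the overlap filter.
  Sites in high-GC targets can draw from a second joint distribution with
  elevated discordance, reproducing the high-GC concordance deficit.
* **Array.** Markers cover a configured fraction of SNP sites (genotypes
  copied from the comparison callset and corrupted at programmed
  discordance/no-call rates), plus on-target homozygous-reference and
  off-target markers; A/B allele order and strand are randomized, and
  confidence scores are drawn mostly below 0.05.

Every generator is a pure function of (configuration, seed): repeated
invocation is identical, and the caller's RNG state is untouched.

### What the generator does not emulate

No linkage disequilibrium, no alignment or mapping-quality structure
(MQ0 values are drawn, not caused), no indel realignment artifacts, no
sequence-context error model, no WGA chimera formation. Passing tests
therefore demonstrate that the *pipeline arithmetic* recovers programmed
truth — not that WGA DNA behaves any particular way on real data.

## Problem sizes and runtime choices

The test suite and the analysis drivers run at scaled-down sizes chosen to
keep the binomial standard errors small relative to the effects being
checked: 40–200 targets (50–180 kbp of target span), 500–8,000 sites for
module tests, 50,000 SNP sites for the parameter-recovery check (3 binomial
standard errors at that size is ≈ 0.17 percentage points of NRS), 100
bootstrap replicates per coverage rung, and 1,000 simulated spectra for the
type-I control. The analysis pipeline writes plain TSV/JSON tables —
plot-ready, no embedded figures — under `results/`.

## Known limitations

* INDEL matching is exact; two records describing the same indel in
  different normalizations count as distinct sites.
* The NRS/NRD engine is site-level and unphased; multi-sample cohort
  concordance is out of scope.
* The recall model's thresholds are not calibrated to any real caller; it
  exists to make the downsampling design testable end to end.
* Whole-genome analyses (the windowed GC track aside) are out of scope:
  every metric is restricted to capture targets.
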