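---
title: "Measuring genotype reproducibility across SNP-array platforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring genotype reproducibility across SNP-array platforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genoconcord)
```

## The problem

Genomic evaluation, parentage testing and association studies all assume
that a genotype is a property of the animal, not of the assay. When the
same DNA is genotyped twice — on one platform, or on chips from two
vendors — the two call sets should agree almost everywhere, and the places
where they do not are informative: they concentrate in SNPs with poor
cluster separation, rare minor alleles, or low per-call quality scores.
`genoconcord` implements that comparison end to end, together with a
simulator that generates matched call-set pairs from a known truth so that
every statistic can be validated against an exact expectation.

## The statistics

All comparisons operate on B-allele counts `c ∈ {0, 1, 2}` over the cells
of an aligned pair (common samples × common, coding-reconciled SNPs).
Missingness is handled by pairwise deletion: a cell contributes only when
both platforms called it, and every summary reports its denominator.

For two call vectors `x`, `y` restricted to pairwise-complete positions:

- **Allele-count correlation**: Pearson `cor(x, y)`. It is undefined
  (`NA`) when either vector is constant — notably monomorphic SNPs — or
  when fewer than two positions remain; `NA` correlations are excluded
  from means and counted, because at zero variance the statistic carries
  no information rather than indicating disagreement.
- **Genotype concordance** `GC = mean(x == y)`.
- **Allele concordance** `AC = mean(shared(x, y)) / 2`, where
  `shared(c₁, c₂) = 2 − |c₁ − c₂|` is the size of the intersection of the
  two allele multisets: identical genotypes share both alleles, a het/hom
  disagreement shares one. The definition extends naturally to opposite
  homozygotes sharing zero alleles — AA vs BB has an empty multiset
  intersection — which also yields the identities used throughout the
  tests: `AC = 1 − mean(|x − y|)/2 = GC + p₁/2`, with `p₁` the fraction of
  one-allele disagreements. `AC ≥ GC` always.

Per-animal and per-SNP summaries are unweighted means across units (each
animal or SNP counts equally); the pooled "overall" statistic over all
cells is reported alongside, since both views answer different questions
(typical animal vs typical genotype). The genotype contingency table
cross-tabulates all compared cells by the two platforms' calls and reports
row percentages; because the natural denominator of the
opposite-homozygote proportion is ambiguous, it is emitted conditional on
the left platform's homozygotes, the right's, and their average.

## Harmonization

Two vendors rarely share an allele-labelling convention, so equal counts
need not mean equal genotypes. Harmonization proceeds in a fixed order:

1. **SNP matching** by identifier, minus an explicit `drop_ids` list (for
   SNPs known to be absent or never called on one side, without modelling
   why). Position-based matching across genome builds is out of scope.
2. **Allele-coding reconciliation.** Per SNP the right dataset's letter
   pair is tested as identity, A/B swap (counts `c → 2 − c`), strand
   complement, and complement-plus-swap. For strand-ambiguous SNPs (A/T,
   C/G) letters cannot distinguish swap from complement; the orientation
   whose B-allele frequency is closer to the left platform's is chosen,
   but only when the left MAF is below 0.4 — near 0.5 both orientations
   fit the frequencies and a wrong guess silently miscodes every
   genotype, so such SNPs are dropped and counted rather than guessed.
   SNPs incompatible under all four transformations are likewise dropped,
   not fatal.
3. **Sample call-rate filtering**, computed on the matched SNP set so the
   rates are comparable across platforms, with a default threshold of
   0.90. Exclusion is symmetric: a sample failing on either platform is
   removed from both, since its comparison cells are untrustworthy on one
   side and unverifiable on the other. The audit records the
   per-platform failing lists and enforces
   `retained = initial − |union|`.

Running matching before call-rate filtering is a deliberate choice the
package tests as a regression: on shared manifests the two orders commute,
and on differing manifests only this order makes per-sample call rates
refer to the same assays on both platforms.

## Stratified views

- **MAF** (from a chosen reference platform): monomorphic SNPs form their
  own bin — their correlation is undefined and their apparent concordance
  behaves differently — and polymorphic SNPs fall into right-closed bins
  of width 0.05, so a SNP at exactly 0.10 lands in (0.05, 0.10].
  Right-closure is a determinism convention, not a scientific claim.
- **Quality score**: SNPs are binned by their mean per-call score
  (default 0.05-wide bins on [0, 1]); per-bin mean allele concordance
  with its SD and SNP count. Orientation is honoured — Illumina GC scores
  are higher-is-better, Affymetrix confidence scores lower-is-better (bin
  order reversed for display).
- **Quality restriction** masks calls on the bad side of a threshold
  (default 0.55, a common GC-score cutoff in association work) and
  recomputes everything downstream, quantifying how much stricter
  quality control would buy.
- **Axiom categories**: per-category unweighted means plus each
  category's share of all SNPs, and the pooled genotype concordance over
  segregating PolyHighResolution SNPs — the restriction a
  quality-conscious downstream analysis would apply. Whether such
  published tables use per-SNP or genotype-weighted means is usually
  unstated; this package uses unweighted per-SNP means and exposes the
  pooled statistic separately.
- **Concordant vs discordant quality**: Welch's unequal-variance
  two-sided t-test on the per-cell score, chosen because the two groups
  differ enormously in size and plausibly in variance. For duplicate
  runs where both replicates carry scores the per-cell statistic is the
  minimum of the two (`platform = "min"`); for cross-platform
  comparisons it is the tested platform's score.

## The simulator

`simulate_dual_platform()` draws per-SNP B-allele frequencies from a
configurable MAF law, genotypes under Hardy–Weinberg equilibrium, and
then corrupts each platform independently:

- **Per-allele errors.** Each of a call's two alleles flips with the
  platform's rate ε, so one-allele miscalls occur at rate ≈ 2ε while
  opposite homozygotes require two flips (≈ ε²). This mirrors the
  empirical signature of array genotyping, where virtually all
  replicate disagreements are het/hom and opposite homozygotes are
  vanishingly rare. A genotype-level error mode exists as a stress test
  in which that suppression is absent.
- **Quality coupling.** Scores are Beta draws with mean ≈ 0.89 for
  correct calls and ≈ 0.85 for erroneous ones (`Beta(8.9, 1.1)` vs
  `Beta(8.5, 1.5)`), a deliberately overlapping pair: quality flags
  errors only statistically, never individually. Lower-is-better
  platforms store `1 − q`.
- **Categories.** Labels follow the configured fractions, whose defaults
  reflect a mid-density custom Axiom array (≈ 73.6% PolyHighResolution,
  4.2% NoMinorHom, ≈ 1.9% MonoHighResolution, ≈ 8.4% CallRateBelowThres,
  ≈ 0.9% OffTargetVariant, ≈ 11% Other). MonoHighResolution labels are
  placed only on truth-monomorphic SNPs (a config error if the requested
  fraction exceeds the monomorphic pool; rare sampling overshoot is
  clamped to "Other"). CallRateBelowThres SNPs receive 0.15 missingness;
  poorly clustering categories receive extra per-allele error.

Default rates are chosen once to emulate a realistic two-vendor
comparison: base ε of 0.001 (left) and 0.0035 (right) so that
well-clustered SNPs agree genotype-wise at ≈ 0.991; category error boosts
(0.015 Mono, 0.011 CallRateBelowThres, 0.074 OffTarget, 0.047 Other) that
reproduce the characteristic quality ordering of Axiom categories; and
missing rates 0.006 / 0.026 matching per-sample call rates of ≈ 0.994 and
≈ 0.974. The default problem size is 84 samples × 51,121 SNPs.

The simulator's own oracle, `expected_pair_stats()`, enumerates the
3 × 3 × 3 kernel (truth genotype × two observations) exactly:
`allele_error_kernel(ε)[t, o]` by binomial enumeration of flips, weighted
by Hardy–Weinberg genotype probabilities at each SNP's frequency. The
validation suite checks that simulated discordance, allele concordance
and opposite-homozygote rates sit within three binomial standard errors
of this expectation at ε ∈ {0.001, 0.01, 0.05} on 500 × 5,000 datasets,
that coupled quality recovers the configured concordant/discordant gap,
and that zero-error simulations give every statistic exactly 1.

**What the simulator does not emulate** — and therefore what passing
tests do not demonstrate about real data: linkage disequilibrium and
pedigree structure (irrelevant to per-cell statistics, but real),
intensity-space cluster geometry (category labels are sampled, not
derived from clustering), batch and DNA-quality effects, informative
missingness beyond the category mechanism, and platform-specific strand
reporting conventions beyond the four letter transformations.

## Numerical and interface choices

- Missing calls are `NA`; a missing call's quality is ignored everywhere.
- PED reading assigns `allele_a`/`allele_b` as the observed major/minor
  letters (frequency ties broken alphabetically, monomorphic SNPs given a
  deterministic placeholder minor letter) unless a manifest fixes the
  coding; call tables may omit allele letters entirely, in which case the
  SNPs are assumed pre-harmonized and are never strand-flipped.
- The long call-table format carries a `#`-prefixed header block
  (platform, orientation, sample list, SNP metadata) so that all-missing
  samples and uncalled SNPs survive a write/read round trip exactly.
- Correlation is declared `NA` when a restricted vector's variance is
  exactly zero (integer data makes this test exact).
- Failures carry classed conditions — `config_error`, `parse_error`,
  `data_error`, `pipeline_error`, `lookup_error` — so callers can react
  to the stage rather than the message; degenerate analyses (no common
  SNPs, no comparable cells, everything filtered) are pipeline errors,
  while an all-SNPs-unresolvable reconciliation returns an empty pair
  with a warning, since dropping is that operation's documented
  behaviour.
- Reports render rates to 4 decimals and percentages to 2 in markdown;
  TSV outputs keep full precision.

## Limitations

Genotype calling itself (GenomeStudio, Axiom clustering) is out of scope:
the package compares call sets, it cannot say which platform is right
when they disagree, and with technical replicates only, truth is
unknowable by design — the simulator exists precisely to supply a truth
for validating the machinery. Chance-corrected agreement (kappa),
haplotype-level comparison and VCF/binary-PLINK input are not
implemented.
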