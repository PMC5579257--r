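---
title: "Screening drug-target gene regions for disease association: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening drug-target gene regions for disease association: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetgwas)
```

## The question the pipeline answers

A drug with known adverse cardiovascular effects interacts with a set of
gene products. If some of those genes also modulate inherited disease risk,
their genomic neighborhoods should carry case-control association signals.
`targetgwas` implements that screen end to end: it takes a drug-gene
interaction table, builds flanked test regions around each target gene,
derives a multiple-testing threshold from the local haplotype-block
structure, runs per-study logistic association, combines studies by
inverse-variance meta-analysis, picks and annotates lead SNPs, and finally
asks whether the target set as a whole is enriched for genes with
disease-associated expression-linked SNPs (eSNPs).

This vignette documents the statistical model at each stage, the tunable
parameters and their defaults, what the synthetic-data generator does and
does not emulate, and the numerical choices and known limitations a user
should be aware of.

## Regions

Each mappable target gene contributes one half-open window
`[max(0, start - flank), end + flank)`. The default flank is 100 kb per
side, i.e. a 200-kb span added around the gene body; the reading in which
the whole *window* is 200 kb wider than the gene is the natural one for a
"200-kb region surrounding the gene", and the alternative (±200 kb) is one
`flank` argument away. Windows are never merged: overlapping regions share
member SNPs, and downstream stages deduplicate fits while reporting hits
per gene (Table-style output is organized per gene, so a shared lead is
reported under both genes with a `shared_lead` flag).

Genes named in the interaction table but absent from the coordinate table
are returned in an `unmapped` list rather than dropped silently — the
mapped count is an analysis result, not a side effect.

## Haplotype blocks and the effective number of tests

SNPs within a region are strongly correlated, so Bonferroni correction on
the raw SNP count would be badly conservative. The pipeline instead counts
haplotype blocks and treats each block as one independent test, a
computationally light analogue of the spectral (eigenvalue-based)
effective-test-count correction, which is also provided as
`meff_nyholt()` for comparison: `Meff = 1 + (M-1)(1 - Var(lambda)/M)`,
clipped to `[1, M]`. The two agree at the extremes (all SNPs independent;
one perfect block), which the test suite checks.

Blocks are detected by the D'-confidence-interval rule of Gabriel and
colleagues, the method behind PLINK's default `--blocks` command:

* For each SNP pair within `max_span` (default 200 kb), the multinomial
  likelihood of the two-locus haplotype counts is evaluated on a grid of
  |D'| in [0, 1] (step 0.001) with allele frequencies held at their
  observed values, normalized over the grid. `CL` is the largest grid value
  with at most 5% cumulative mass strictly below it and `CU` the smallest
  with at least 95% at or below it — one-sided 5% bounds, the
  Gabriel/Haploview convention.
* A pair is **strong LD** when `CL >= 0.70` and `CU >= 0.98`, shows
  **recombination** when `CU < 0.90`, and is otherwise uninformative. Pairs
  where either MAF is below 0.05 are uninformative.
* A candidate block is an interval whose outermost pair is strong and in
  which at least 95% of informative pairs are strong; candidates are
  accepted greedily by decreasing SNP count, ties to the left, without
  overlap.

Two deliberate simplifications: haplotype counts come from the phased
reference panel when phase is available (the EM fallback
`two_locus_em()` handles unphased input), and Haploview's special-cased
thresholds for 2- and 3-marker blocks are *not* reproduced — one uniform,
configurable rule is used instead. The screen only consumes the block
*count*, and the detector is validated against exhaustive interval
enumeration on every window of up to 12 SNPs rather than against PLINK
bit-for-bit.

The threshold is `alpha_family / meff` with `meff` the block count; SNPs
outside any block can be counted as extra independent tests via
`include_singletons` (the narrative phrase "number of independent SNPs" is
ambiguous on this point, so both modes exist, with the block-count-only
default matching the published arithmetic: 81,703 SNPs, 3,131 blocks,
0.05/3131 ≈ 1.6e-5). `floor_pow10` rounds the threshold down to the
nearest power of ten (3,131 blocks then give 1e-5); it defaults to off
because flooring is a presentation convention, not a statistical one.

## Per-study association

For each SNP, `logit P(case) = b0 + beta·g + bs·sex + ba·age` is fit by
IRLS (tolerance 1e-10, at most 25 iterations), with age entering
untransformed. Individuals with missing genotype are dropped per SNP;
missing covariates drop the individual. Monomorphic SNPs are flagged
rather than fit, and separation (non-convergence or |beta| > 15) flags the
record `unstable`; flagged records are excluded from meta-analysis. No
genomic-control correction is applied anywhere — `lambda_gc()` is reported
for diagnostics only. With 500 independent null SNPs the observed lambda
is tested inside a generous [0.9, 1.1] band, reflecting the sampling noise
of a median at that problem size.

## Meta-analysis

Study effects are first aligned to a common allele orientation (swapped
records flip `beta` and complement the frequency; irreconcilable pairs are
dropped and logged; A/T and C/G pairs are dropped only when
`drop_ambiguous` is set, since the synthetic generator never emits them).
Then, per SNP:

* fixed effects: `beta_FE = sum(w beta)/sum(w)`, `w = 1/se^2`;
* Cochran's `Q = sum w (beta - beta_FE)^2` against chi-square(k-1);
* DerSimonian–Laird `tau2 = max(0, (Q - (k-1))/(sum w - sum w^2/sum w))`
  and random-effects weights `1/(se^2 + tau2)`.

The model actually reported per SNP is random effects when
`p_het < 0.01`, fixed otherwise; both are always emitted so the gate is
auditable. Across *stages* (e.g. a discovery meta-analysis plus a de novo
genotyping stage) the combination is always fixed-effects, and stage
sample sizes are summed into the report header; duplicate study labels
across stages are an error because the stages must be non-overlapping.
DL's small-K downward-bias-plus-truncation behavior is known; the test
suite tolerates (and documents) relative bias under 25% at K = 10.

## Screening, risk alleles, proxies, annotation

Within each region the minimum-p SNP below the threshold becomes the lead
(ties: smaller position). Leads are oriented so the risk allele is the one
more frequent in cases (`OR = exp(beta) >= 1`); a beta of exactly zero is
flagged as arbitrary orientation. Proxies are all panel SNPs with
`r2 > 0.8` (strict) to the lead, computed on the reference panel rather
than study genotypes, mirroring the use of an external LD reference.
Annotation is a join over `{lead} ∪ proxies`: eQTL records (direction
re-expressed relative to the risk allele), regulatory-element flags, and
trait associations kept only when flagged disease-related *and*
`p < 1e-3`. Disease-relatedness of a trait is an input column — curation
belongs to the data, not the code. A `gw_significant` flag marks leads
passing the conventional 5e-8 level as a secondary descriptor; the primary
criterion remains the block-based threshold.

## eSNP enrichment

A gene is *flagged* when at least one of its eQTL SNPs has association
`p` below the main-analysis threshold. The 2×2 table opposes flagged
target genes to flagged genes of a pathway-universe background (the union
of the gene sets in a GMT file); the default excludes target genes from
the background so the table is disjoint, and `overlap_mode = "inclusive"`
supports the other reading — on the published counts (3 of 43 targets vs
1.5% of 7,076 background genes, i.e. 106 after round-to-nearest) both
readings round to the same two-decimal p-value, which the tests verify.
The test is the one-sided Fisher exact (upper hypergeometric tail,
enrichment alternative); `fisher_one_sided()` is checked against full
enumeration for every population up to 60.

## The synthetic-data generator

The generator exists so the whole pipeline can be validated against known
truth; its defaults are the study conditions used throughout the test
suite.

**LD model.** A founder mosaic: each of 48 blocks carries a small set of
founder haplotypes (2 by default) with frequencies drawn from a uniform
simplex shifted so every founder keeps frequency at least `maf_min`; each
of the 1,000 panel haplotypes copies one founder per block, independently
across blocks. Within-block LD is therefore perfect for two founders and
strong for more; between blocks there is exact linkage equilibrium. A
coalescent simulator would be more realistic but would not provide exact
block truth; the screen's method only assumes that block structure exists.
Block-truth recovery is scored by *purity*: a SNP counts as correctly
assigned when its detected block contains no SNP from another truth block
— merges across truth blocks are errors, while splits and singletons are
not, because with 3–4 founders genuinely equilibrium pairs occur inside a
truth block and the Gabriel rule is right to split there.

**Cohorts.** Genotypes are two panel haplotypes drawn independently
(Hardy–Weinberg at panel frequencies). Disease follows a logistic
liability with planted per-allele log-odds (perturbed per study by
`N(0, between_study_sd)` to emulate heterogeneity), sex (Bernoulli(0.5),
log-odds 0.25) and standardized age (Normal(60, 8) truncated to [30, 90],
log-odds 0.3 per decade); the intercept solves a baseline prevalence of
0.3 at covariate means — a moderately common disease, which keeps
rejection sampling of the case/control quotas efficient while preserving
the covariate-disease structure (retrospective allele sampling would not).
Optional uniform genotype missingness exercises the exclusion path.

**Fixtures.** Ten target genes (4-kb bodies, centers at least 50 kb
apart; genes carrying a planted effect are centered on their planted SNP)
and 200 background genes, a drug-gene interaction table, a pathway GMT
over the background universe, an eQTL table in which every target gene's
local SNPs are its eQTLs (so a planted association is discoverable as an
eSNP signal) and every background gene gets one random SNP, a trait table
with disease-related records at the planted SNPs plus decoys, and a JSON
ground-truth manifest.

**What passing tests do not show.** The generator has no population
stratification, relatedness, imputation uncertainty, allele-frequency
spectrum realism, X chromosome, or strand ambiguity; calibration and
recovery results on it demonstrate correctness of the statistical
machinery under its assumptions, not robustness to confounding in real
cohorts.

## Problem sizes and reproducibility

The validation suite runs at sizes chosen to make Monte-Carlo bands
meaningful while staying desk-scale: the block detector is compared to
brute force on 1,000 random windows of up to 12 SNPs; null calibration
uses 4 studies of 1,000/1,000 over 500 independent SNPs (pooled per-study
p-values give a ±0.01 two-sigma band around 0.05); effect recovery uses
200 replicates of 2,000/2,000 at MAF 0.3; the end-to-end screen runs 50
seeded replicates of the default configuration with odds ratios of 1.3
planted in 3 of 10 regions, requiring full recovery with no false region
in at least 90% of seeds — the residual false-positive rate is exactly the
family-wise alpha the threshold construction is designed to control.
Every generator is a pure function of its seed; `scripts/acceptance.R`
re-derives all headline numbers from scratch for any seed.

## Known limitations

* The D' confidence bounds use a likelihood grid with frequencies fixed at
  their observed values; very small samples (a handful of haplotypes) make
  the bounds wide but still data-dominated — at 8 equilibrium haplotypes
  the upper bound reaches ≈ 0.58, wide enough to be uninformative for the
  strong-LD rule yet narrower than the most pessimistic reading of "small
  samples cannot exclude high D'".
* Exact PLINK/Haploview block output is not a goal; only the block count
  feeds the analysis.
* The meta-analysis assumes summary statistics with well-behaved standard
  errors; records flagged monomorphic/unstable upstream are excluded
  rather than repaired (no Firth correction).
* Fisher enrichment treats genes as exchangeable units; gene length and
  eQTL density confounding are not modeled (the synthetic null shows the
  test holds its size under exchangeability).
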