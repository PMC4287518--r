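---
title: "Methods: integrated cis-QTL, eQTM and variance-partition analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated cis-QTL, eQTM and variance-partition analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regulomeqtl)
```

This vignette is the package's own account of the statistical models it
implements, the assumptions behind them, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the numerical choices that make results reproducible.

## The scientific setting

The package targets a common integrated study design in regulatory
genomics: for the same individuals one has genome-wide SNP dosages,
array-based DNA methylation (beta values in [0, 1] per CpG site) and
array-based gene expression (log2 intensities per probe), collected in two
or more independent adult cohorts, with an additional fetal comparison
group and, for one cohort, several tissues per individual (liver, muscle,
subcutaneous and visceral adipose tissue). The questions it answers:

1. Which CpGs and genes differ between developmental groups, and how does
   the direction of methylation change depend on CpG island context?
2. Which SNPs drive expression (cis-eQTL) or methylation (cis-meQTL) in
   adults, combining cohorts by meta-analysis with permutation-based FDR?
3. Which CpGs correlate with nearby gene expression (eQTM), and how does
   the sign of that correlation depend on correlation strength and
   distance?
4. How much expression variance do the SNP and the CpG(s) explain jointly
   and uniquely (nested linear models)?
5. How well do these associations travel across tissues, and are
   developmental-stage-specific genes enriched for genetic control?

## Differential analysis

Per feature, a Welch unequal-variance two-sided t-test compares fetal
against adult samples, on beta values for methylation and log2 intensities
for expression. Welch's test is the conservative default for small,
imbalanced groups with no variance-homogeneity guarantee; moderated
(empirical-Bayes) variants are deliberately out of scope. The effect is
always fetal minus adult, so "hypomethylated" and "down-regulated" refer to
the fetal state. Multiple testing is controlled by Benjamini–Hochberg
step-up per data type, and significance additionally requires a minimum
effect: |Δβ| > 0.2 (methylation) or |log2FC| > 1.0 (expression), both
configurable. The dual threshold means the significant set is monotone
non-increasing in either threshold and in alpha.

Zero-variance features in both groups get p = 1 with a warning rather than
an error: constant probes carry no evidence either way. Direction classes
of the gene-level DE ∩ DM intersection partition the genes; a gene whose
probes (or CpGs) disagree in direction is reported as `discordant` rather
than forced into a class, since multi-probe genes with genuinely opposing
probe-level changes occur in real arrays.

The CpG-island contingency analysis tabulates significant CpGs as
(hypo/hyper in fetal) × (island/shore/shelf/other) and uses Pearson's
chi-squared without continuity correction — the counts at a genome-wide
scale are large, and the uncorrected statistic matches the textbook
Σ(O−E)²/E that the tests verify cell by cell. Tables with an empty row or
column report an undefined statistic with the per-class fractions intact.

## cis-QTL mapping

**Pair universe.** SNP–feature pairs within a ±250 kb window, the
conventional cis bound for array-based QTL studies. The anchor of a point
feature is its position; of an interval feature (expression probe), the
interval midpoint rounded down — the symmetric choice when the platform
does not supply a single coordinate. The window bound is inclusive, so
counts are exactly reproducible. For meQTL mapping, pairs whose SNP lies
inside the target CpG probe's hybridisation interval (1-based inclusive on
both ends) are removed first, because a variant under the probe perturbs
hybridisation directly and such "associations" are artefacts.

**Association statistic.** Spearman rank correlation of trait on additive
dosage (0/1/2), with average ranks for ties, two-sided p by the t
approximation, and z = signed normal quantile of p. Rank correlation is
robust to the heavy-tailed intensity distributions of arrays and treats
the dosage monotonically without assuming linearity on the measurement
scale; Pearson is available via `statistic = "pearson"` for users who have
transformed their data. Missing dosages are mean-imputed per SNP within
cohort for the computation only — never written back — which at the
default missingness cap (≤ 5%) perturbs ranks negligibly.

**Meta-analysis.** Cohort z-scores combine with √n weights:
Z_meta = Σ √n_i Z_i / √Σ n_i. This is the standard sample-size-weighted
scheme for rank-based statistics where per-cohort effect variances are not
modelled; it reduces to the single-cohort z for one cohort and is
invariant to cohort order. Cohorts are assumed non-overlapping (distinct
biobanks) and effect-homogeneous up to additive batch offsets, which rank
statistics absorb.

**Permutation FDR.** The null is generated by shuffling the sample linkage
between genotypes and traits within each cohort, which preserves the
trait–trait and SNP–SNP correlation structure while destroying genuine
genotype–trait coupling. For each feature the top |Z_meta| across its cis
SNPs is the summary statistic; with B permutations,
FDR(t) = mean over permutations of #{null tops ≥ t} / #{observed tops ≥ t},
capped at 1. A feature is significant when the FDR at its top statistic is
below alpha, and pair-level significance extends to all pairs whose
|Z_meta| clears the smallest significant top statistic. FDR granularity is
the feature (probe or CpG) because unique features are the natural unit
for counting discoveries; pair lists derive from the feature threshold.
The default B = 10 is deliberate: with hundreds to thousands of features,
each permutation contributes that many null top statistics, so the pooled
null is dense enough for stable FDR estimates at alpha = 0.05 while
keeping the scan fast. The raw counting estimator is reported without
monotonisation; in practice it is near-monotone and the choice is
documented so counts are reproducible.

## eQTM mapping

CpG–probe pairs within ±250 kb, Spearman correlation across adult
samples, and a per-pair permutation p with the add-one estimator,
p = (1 + #{|ρ_null| ≥ |ρ_obs|}) / (1 + B), which is never exactly zero and
is bounded below by 1/(1+B). The default B = 999 is affordable here
because no meta-analysis or per-feature maximisation is involved. The
significance unit is the pair (not the feature), matching how
methylation–expression associations are counted; a BH q over the
permutation p-values is reported alongside so users can apply either
convention. Distances are signed as CpG position minus probe midpoint
under a plus-strand convention; probe strand is not modelled, a documented
limitation that only affects the sign, not the magnitude, of the distance
summaries.

## Variance partitioning

For each probe with both a significant eQTL and at least one significant
eQTM, four nested OLS models are fitted: SNP only, top CpG only,
SNP + top CpG, SNP + all eQTM CpGs. The representative SNP is the
strongest significant eQTL by |Z_meta| and the representative CpG the
strongest eQTM by |ρ| — the natural "top association" choice when the
upstream scan already ranks candidates. Genotype enters as additive
numeric dosage, consistent with the rank-based discovery model. R² is
unadjusted (raw proportions of variance are the quantity of interest);
adjusted R² is reported alongside for transparency.

Unique contributions are semi-partial R² differences
(unique_snp = R²_snp+cpg − R²_cpg, and symmetrically), and the shared
component R²_snp+cpg − unique_snp − unique_cpg may legitimately be
negative under suppression; it is reported with a flag rather than clipped.
Collinear CpG columns are dropped by QR pivoting, which guarantees the R²
chain respects nesting to numerical tolerance (asserted at 1e-10 in the
tests); when the all-CpGs model adds no independent predictor beyond
SNP + top CpG the F-test is undefined and reported as `NA`. F-test
significance uses two tiers (0.05, 0.005) rendered as `*`/`**`.

## Cross-tissue sharing and matched-probe enrichment

Overlap across tissues is exact set algebra over association keys
(SNP–feature pair for QTLs, CpG–probe pair for eQTMs). Replication is
strict — significant in both tissues under the same machinery — because a
relaxed lookup (nominal p in the second tissue) inflates apparent sharing;
the report structure makes a lenient re-analysis straightforward since
per-tissue results carry full statistics. Direction concordance is the
fraction of multi-tissue keys whose effect sign is identical in every
tissue carrying them; discordant keys are listed with their per-tissue
signs. Positional context of discordant meQTL CpGs (outside gene bodies;
exon vs intron) is reported as descriptive counts with plain chi-squared
tests.

Matched-probe enrichment asks whether a target probe set is enriched for a
binary property relative to probes with comparable expression level and
variability: each target greedily takes its nearest unused pool probe in
z-scored (median, SD) space, in a random target order under a fixed seed,
without replacement; ties break on pool order. Euclidean distance on the
two z-scored axes is the simplest metric consistent with "similar median
and SD", and greedy matching without replacement guarantees the matched
set has exactly the target set's size. The enrichment is the ratio of
flagged fractions with a 2×2 chi-squared test; a zero-flagged matched set
reports an infinite fold with the raw counts.

## The synthetic-data generator

`sim_config()` + `simulate_study()` generate a complete study: sample
sheet, genotypes, methylation, expression, and a truth table listing every
planted effect exactly once. The default design mirrors the two-cohort
setting: cohort A with 96 adult and 14 fetal liver samples, cohort B with
85 adults sampled in four tissues; genotypes are constant across tissues
of an individual while methylation/expression noise is redrawn per tissue.

Generative model, per feature and sample:

- Genotypes: per-SNP allele frequency uniform on `maf_range`
  (default [0.05, 0.5]), genotypes binomial(2, p) — Hardy–Weinberg by
  construction. No linkage disequilibrium.
- Methylation: latent m = μ + a·z(dosage) + fetal shift + cohort offset +
  Gaussian noise, mapped to beta = 2^m/(2^m+1) (the standard
  M-value-to-beta relation). Additive genetic effects are natural on the
  latent scale while the tests operate on beta values.
- Expression: y = μ + b·z(dosage) + c·z(latent m) + fetal log2FC + cohort
  offset + Gaussian noise.

Slopes are standardized (in residual-SD units), so a planted slope b
induces correlation b/√(1+b²) regardless of allele frequency. Defaults
that encode the emulated study's reported proportions: differentially
methylated CpG fraction 0.08 and differentially expressed probe fraction
0.07 (the approximate genome-wide fractions in the emulated setting);
island CpGs hypomethylated in fetal samples with probability 0.86 versus
0.5 elsewhere; negative eQTM fraction 0.584; opposite-direction fraction
0.7 for SNPs shared between a meQTL and an eQTL of the same gene; tissue
sharing 0.45 (eQTL), 0.70 (meQTL), 0.04 (eQTM); cross-tissue sign flips
2%. Purely generative knobs with no reported counterpart were chosen once
as field-realistic: latent noise SD 1 and baseline spread SD 2 give
beta-value distributions spanning [0.1, 0.9] like array data; expression
baselines N(8, 2) match log2 intensity ranges of bead arrays; cohort
offsets SD 0.3 create visible but benign batch structure; the fetal latent
shift 2.5 makes expected |Δβ| exceed the 0.2 threshold for affected CpGs.

Features are placed uniformly on four synthetic chromosomes with ~25 kb
average SNP spacing so every probe has a dense cis SNP neighbourhood;
planted QTLs use the nearest SNP within the window. What the generator
does **not** emulate: LD structure between SNPs, trans effects,
probe-type chemistry mixtures of 450K arrays, cell-type composition,
non-Gaussian intensity noise, or realistic gene structure. Passing tests
therefore demonstrate correctness of the statistical machinery and
calibration under a clean generative model — not robustness to every
artefact of real array data.

## Numerical and reproducibility choices

- Coordinates are 1-based inclusive internally; BED export converts to
  0-based half-open.
- Every stochastic routine takes an explicit seed; fixing the seed fixes
  every output byte. `simulate_study()` uses one seeded stream for all
  three data types.
- Correlations are computed as inner products of unit-normalised centered
  ranks, which matches `cor(method = "spearman")` to 1e-12 and
  vectorises over the whole pair list; |ρ| is clamped at 1 − 1e-15 before
  the t transform and z-scores at ±38.4 (the normal-quantile underflow
  bound).
- All filters (variable CpGs, SNP QC) are idempotent; QC uses MAF ≥ 0.05,
  exact-test HWE p ≥ 1e-6 (standard heterozygote-count enumeration) and
  missingness ≤ 5% by default. The variable-CpG beta-SD threshold of 0.02
  is a pragmatic stand-in for array "variable probe" filters whose exact
  form varies between studies; it is configurable and the retained count
  is always reported.
- Test problem sizes: the calibration suite uses 500-probe, n = 150
  two-cohort studies across 20 seeds and 10 permutations; parameter
  recovery uses n = 10,000 single-shot regressions. These sizes give
  stable Monte-Carlo estimates (binomial SE < 0.01 for the recovered
  fractions) at desk scale.

## Known limitations

- No covariate regression (age, sex, latent factors) in the QTL models;
  the rank statistic absorbs monotone per-cohort batch effects but not
  sample-level confounders. This is an extension point, not a design
  claim.
- No LD-aware clumping of QTL pairs; "unique SNPs" in overlap analyses
  means exact identity, not proxy equivalence.
- No causal ordering of methylation versus expression; eQTMs are
  correlations.
- The permutation FDR's raw counting estimator can be locally
  non-monotone at small permutation counts; significance is decided per
  feature at its own statistic, as documented above.
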