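---
title: "Methods: models, calibration and design choices in clinalscan"
author: "clinalscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, calibration and design choices in clinalscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`clinalscan` analyses georeferenced SNP panels for signatures of clinal
adaptation. This vignette documents the statistical models it
implements, the calibration of its synthetic-landscape generator, the
numerical choices that matter, and the limits of what its tests
demonstrate.

## The data model

The central object is a samples × variants matrix of diploid ALT-allele
dosages (0/1/2). Missing calls are `NA_integer_` — R's native masked
sentinel, distinct from dosage 0 — and every statistic in the package
masks missing calls explicitly rather than imputing silently (only the
kinship/PCA/RDA matrix operations mean-impute, which is the standard
treatment there). Variants are kept sorted by natural chromosome order
("Chr2" before "Chr10") and position. All internal interval arithmetic
is 0-based half-open; GFF3 (1-based closed) and BED (0-based half-open)
are normalized on import, and a SNP at 1-based position p occupies
[p−1, p).

## Population-genetic statistics

**Nucleotide diversity.** Per site, the unbiased average pairwise
difference 2·p̂·q̂·2n/(2n−1) over the 2n called allele copies; windows
tile each chromosome from position 0, half-open, and report the summed
site diversity divided by the window width (per-bp convention; the
trailing partial window keeps the nominal width as denominator, which
slightly deflates diversity there — documented rather than hidden, as
window-edge conventions differ between tools).

**Weir–Cockerham F<sub>ST</sub>.** The 1984 variance components a
(among populations), b (among individuals within populations) and c
(within individuals) for r populations with unequal sample sizes,
computed from per-population allele frequencies and heterozygote
proportions. Combined estimates are ratios of sums Σa⁄Σ(a+b+c) (the
weighted estimator), per-site values are emitted unclamped — negative
estimates are part of the estimator's unbiasedness and are not
truncated.

**Tajima's D.** Per window, D = (π_sum − S/a₁)/√(e₁S + e₂S(S−1)) with
the 1989 constants. The chromosome count is twice the mean non-missing
diploid count over the window's segregating sites (rounded); with
complete (imputed) data this reduces to 2n, and the rule gives masked
data a defined behavior. Windows with fewer than `min_sites`
segregating sites (default 3) report `NA`: the D variance estimate is
meaningless on one or two sites.

**LD decay.** Pairwise squared Pearson correlation of dosage vectors on
pairwise-complete samples, same-chromosome pairs up to a maximum
distance, binned means, and a cubic smoothing spline over bin midpoints
weighted by pair counts. Threshold crossings (e.g. r² = 0.1) are read
off the smoothed curve by linear interpolation; both raw and smoothed
curves are returned so the smoothing is auditable.

**Inbreeding.** Method-of-moments F = 1 − O(het)/E(het), with E(het)
the sum of 2p̂q̂ over the sample's non-missing sites using panel-wide
frequencies. In a structured panel this estimate absorbs the Wahlund
effect; on the package's three-group test landscapes the upward bias is
within ±0.05 of the simulated selfing level, which is the tolerance the
tests use.

## Population structure

PCA centers dosages by 2p̂ (optional 1/√(2p̂q̂) scaling) and
decomposes by SVD with a deterministic sign convention (largest-|loading|
element positive). DAPC-style clustering runs multi-start k-means
(stats::kmeans, 10 starts, seeded) on retained PCs for k = 1..k_max and
selects k by the BIC n·log(WSS/n) + k·log(n) (ties to the smallest k),
then fits linear discriminant axes (MASS::lda) on the selected
partition. The number of retained PCs defaults to enough PCs for 80% of
the leading-component variance, a choice made a priori since no
standard exists.

A known limitation, measured during development: the argmin of this BIC
is reliable for panels up to roughly 200 samples at the package's
simulated marker densities, but for larger panels the BIC tail flattens
and argmin drifts to k > k_true (the classic "inspect the elbow"
caveat). The structure-recovery analyses in the tests and the
acceptance script therefore run at n = 150, m = 1500, where selection
is stable; for large real panels the full BIC curve in the result
object should be inspected rather than trusting argmin.

Neighbor joining delegates to `ape::nj` on 1 − mean-IBS distances;
negative branch lengths (possible on non-additive matrices) are clamped
to zero with the magnitude transferred to the sibling branch, and the
tree is flagged when this happened.

## RDA variance partitioning

The genotype matrix Y (column-centered, not variance-scaled by default
— a flag enables scaling; the choice matters little for dosage data on
a common scale) is regressed on standardized predictor sets via the QR
decomposition of the n × p predictor matrix, so the m ≫ n case costs
O(n·p·m). R² = trace(SS_fit)/trace(SS_tot), adjusted by Ezekiel's
formula. The two-set partition is

* [a] = adjR²(climate+space) − adjR²(space) — climate unique,
* [c] = adjR²(climate+space) − adjR²(climate) — space unique,
* [b] = adjR²(climate) + adjR²(space) − adjR²(climate+space) — collinear,
* residual = 1 − adjR²(climate+space),

which sums to 1 exactly by construction. Negative adjusted fractions
are reported as computed (vegan does the same; clamping is display
only). The test suite cross-checks the partition against
`vegan::varpart` to 1e-8.

The permutation test randomizes *individuals*: rows of Y are shuffled
jointly against both predictor sets, [b] recomputed per permutation,
and the one-sided upper-tail add-one p-value reported. Upper-tail
because the scientific hypothesis is *excess* climate-collinear
structure. Permuting climate conditionally on space is a different
(conditional) test and is deliberately not the default. Doubling the
permutation count changes p by at most the add-one resolution;
p-values are seeded and exactly reproducible.

## Association models

**BLUPs.** Multi-garden records are fit as y = μ + garden(random) +
accession(random) + residual by REML through `lme4::lmer`; reported
values are μ plus the accession BLUP. A printed model that omits the
accession term could not yield per-accession predictions, so accession
is modeled as random; with a single garden the garden variance is fixed
at zero with a warning. On balanced single-garden designs the result
equals the closed-form shrinkage μ + rσ²_g/(rσ²_g+σ²_ε)(ȳᵢ − μ) to
1e-6, which the tests verify.

**Mixed-model scan.** VanRaden kinship K = ZZ′/2Σp̂q̂. The scan
eigendecomposes K once, REML-profiles δ = σ²ₑ/σ²_g on a 100-point
log-δ grid over e⁻¹⁰..e¹⁰ with local `optimize` refinement
(deterministic and derivative-free), then tests each SNP by weighted
least squares in the rotated basis with fixed intercept + first three
genotype PCs (+ forced cofactors), Wald t-tests. When K = I the scan
reduces to OLS exactly (verified to 1e-6), and on pure-noise traits the
genomic inflation factor stays in [0.8, 1.2] at the tested design
points.

**MLMM.** Forward stepwise: add the most significant SNP below the
threshold (default Bonferroni 0.05/m; the threshold is configurable
since reasonable marker-count conventions differ) as a fixed cofactor,
re-estimate variance components, drop any cofactor whose own Wald p
rises above the threshold, stop at `max_cofactors` or when nothing is
significant. The reported model is the last forward step; the inclusion
path is attached for auditing.

**GLM scan.** Environment regressed on dosage with no structure
correction — deliberately, because climate-correlated structure makes
corrected scans blind to clinal signal; the cost is confounding, which
is why its outliers feed an *enrichment* test rather than being
interpreted per-SNP. Outliers are the empirical top quantile (type-1
quantile, ties included).

## Enrichment

A gene is hit when its interval lies within `window_bp` (default
100 kb) of an outlier SNP, distance measured to the nearest gene
boundary (not midpoint). Chi-square enrichment compares hit proportions
between a-priori candidates and all annotated genes (Pearson, no
continuity correction). The Tajima's-D test counts candidates
overlapping high-D windows and compares against `n_perm` uniform
without-replacement draws of equally many genes — permuting gene
identity, not window position. Gene draws are not matched for length or
chromosome by default (a chromosome-matched option would be a natural
extension); at the package's simulated gene-length scales the
unmatched null is exact by construction, which the calibration tests
confirm. "High-D" defaults to D > 0, but when the genome-wide D
distribution is shifted (structured or non-equilibrium panels) a
percentile threshold discriminates better; the enrichment analyses in
the tests and acceptance script use the genome-wide upper quartile,
mirroring how D scans are reported in percentiles.

## The synthetic landscape generator

The generator is the package's study design, not a tuning knob; its
defaults were fixed before the test thresholds were evaluated and
encode the regime of a West-African-style landrace panel:

* three genetic groups from the Balding–Nichols model at Wright's
  F = 0.2 around Uniform(0.05, 0.95) ancestral frequencies (the
  observed among-group Weir–Cockerham F<sub>ST</sub> lands within
  ±0.05 of the target);
* samples in group latitude bands; one primary climate variable linear
  in latitude with noise calibrated so cor(climate, latitude) hits a
  target (default −0.86), plus nine noisy copies (r ≈ 0.8) standing in
  for a correlated climate-variable block;
* within-individual inbreeding F = 0.8 (genotype frequencies
  p² + pqF, 2pq(1−F), q² + pqF), mimicking a selfing crop;
* optional clinal loci whose allele frequency follows a
  group-independent logistic cline on the standardized climate;
* an additive trait with configurable heritability, emitted as
  per-garden records y = μ + genetic value + garden effect + residual
  with the genetic share of within-garden variance equal to h².

Three canned scenarios (`landscape_scenario()`) fix the design points
used throughout testing: `"null"` (no clines, climate decoupled from
space and genotype, panmictic) for calibration; `"clinal"` (8% of SNPs
with slope-2 clines, spatially unstructured groups), calibrated once
during development so the expected climate-collinear fraction [b] is
≈ 0.03 — the regime where climate-collinear variance is small but
significant; and `"clinal-strong"` (clustered slope-3 clines on a
panmictic background) for enrichment power analyses. Balding–Nichols
was chosen over a coalescent-with-migration model because the analyses
characterize structure by F<sub>ST</sub>, not demography, and the
F<sub>ST</sub>-targeted draw makes that property exact and cheap.

The coalescent site simulator (`simulate_coalescent_sites`) is a
standard Kingman tree with infinite-sites Poisson mutation at rate
θ/2 per branch-length unit; E[S] = θΣ1/i and a near-zero mean Tajima's
D are verified properties.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: linkage and recombination maps (sites are
exchangeable given structure; LD exists only where planted), GBS
genotyping error and allele dropout, site-frequency spectra of real
demographies (ancestral frequencies are uniform, so rare variants are
underrepresented relative to a real GBS panel), isolation-by-distance
within groups, and multi-trait genetic correlation.

## Problem sizes and numerics

Simulation-based checks run at fixed design points chosen as the
package's own desk-scale study conditions: null calibration at
n = 120 samples × 2,000 SNPs over 100 replicate datasets with
199-permutation tests; signal recovery over 20 seeds at the same size;
structure recovery at n = 150 × 1,500 over 20 seeds; GWAS power at
n = 400 × 5,000 over 50 seeds; 1,000 coalescent replicates at n = 10,
θ = 5. Null rejection *rates* (as opposed to per-seed power) are
estimated over 100 seeds, since a 20-draw binomial cannot resolve a
≤10% bound.

Numerical conventions worth knowing: permutation p-values always use
the add-one rule, so the smallest attainable p is 1/(n_perm+1);
rank-deficient predictor sets are reduced by pivoted QR with a warning;
zero-variance SNPs are skipped in scans; all-tied outlier p-values flag
everything with a warning; eigenvalues of K are floored at zero with a
warning if the matrix is numerically non-PSD; and every stochastic
routine takes an explicit integer seed, with the pipeline recording
each stage's seed in its JSON summary.
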