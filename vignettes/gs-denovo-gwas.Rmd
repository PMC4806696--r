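---
title: "Genomic selection with de novo GWAS-derived fixed effects: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic selection with de novo GWAS-derived fixed effects: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsdenovo)
```

## The problem

Genomic selection (GS) ranks selection candidates in a breeding program by
their genome-estimated breeding values (GEBVs), predicted from genome-wide
markers without phenotyping every candidate. Standard RR-BLUP/GBLUP treats
all marker effects as exchangeable random draws, which is efficient for
polygenic traits but dilutes the signal of individual medium-to-large-effect
QTL. `gsdenovo` implements the hybrid strategy: run a mixed-model GWAS on
the *training* portion of each cross-validation fold, promote a handful of
clearly associated SNPs to *fixed* effects, and fit the rest of the genome
as the usual genomic random effect — with the promoted SNPs removed from the
relationship matrix so their signal is not counted twice.

## The model

The prediction model is the single-random-effect linear mixed model

$$y = X\beta + Zu + e, \qquad u \sim N(0,\, G\sigma^2_u), \qquad
  e \sim N(0,\, I\sigma^2_e),$$

where $y$ holds the adjusted training phenotypes (one value per line, so $Z
= I$ here), $X$ is an intercept column plus the raw allele-dosage columns
(0/1/2) of the selected fixed-effect markers, and $G$ is the VanRaden
method-1 genomic relationship matrix,

$$G = \frac{WW'}{2\sum_j p_j(1-p_j)},$$

with $W$ the dosage matrix column-centered by $2p_j$ and $p_j$ the observed
alternate-allele frequency. Markers fitted in $X$ are excluded from $W$.
With no fixed markers the model is exactly standard RR-BLUP; the package
enforces this reduction to machine precision (`fit_rrblup_fe` with an empty
fixed set *is* the plain path).

### REML, in one dimension

Writing $\lambda = \sigma^2_e/\sigma^2_u$ and eigendecomposing $G = UDU'$
once per line set, the restricted likelihood profiles to a 1-D function of
$\lambda$. `fit_lmm_reml` maximizes it over a 100-point grid on
$\log_{10}\lambda \in [-5, 5]$ followed by Brent refinement to a relative
tolerance of $10^{-8}$; $\beta$ is the GLS estimate at the optimum and $u$
the usual BLUP. Variance components are kept non-negative by construction
(the ratio is optimized, the scale recovered from the profiled closed
form). A perfect linear fit ($\mathrm{RSS} \le 10^{-12}\,\mathrm{SS}_y$)
short-circuits to OLS with both components zero. The test suite checks the
optimizer against a brute-force dense-matrix likelihood grid at 0.1%
resolution.

### Heritability

`estimate_h2` fits the intercept-only model to per-line least-squares means
and reports narrow-sense heritability as additive genetic variance over
total phenotypic variance. One subtlety matters in inbred panels: with the
VanRaden denominator the diagonal of $G$ averages about $1+F$ (about 2 for
fully inbred lines), so $\sigma^2_u$ is additive variance *per unit of G*
and the additive variance in the population is
$\sigma^2_u \cdot \overline{\mathrm{diag}(G)}$. The reported
$h^2 = \sigma^2_u\,\overline{d} / (\sigma^2_u\,\overline{d} + \sigma^2_e)$
uses that scaling; the naive ratio $\sigma^2_u/(\sigma^2_u+\sigma^2_e)$
would understate $h^2$ by roughly $h^2(1-\overline{d}^{-1})$ in inbred
material.

## GWAS and fixed-effect selection

Each marker is tested one at a time as an extra fixed column on top of the
covariates (intercept by default), with the kinship random effect
controlling for family structure, and a 1-df Wald test on its coefficient.
Two modes are provided:

* `exact_per_marker` (default): the variance ratio is re-optimized for every
  marker, by argmax over a shared 121-point $\log_{10}\lambda$ grid
  evaluated vectorized across all markers. The grid spacing (0.083 decades)
  is far below the sensitivity of the Wald p-value to $\lambda$.
* `p3d`: the ratio is frozen at the null-model REML fit. This is the
  classical population-parameters-previously-determined shortcut — one to
  two orders of magnitude faster and rank-identical to the exact mode for
  the vast majority of marker pairs (enforced by test). The cross-validation
  experiments shipped in the test-and-acceptance layer use this mode.

Selection of fixed effects then proceeds in the steps the method
prescribes:

1. **FDR.** Benjamini–Hochberg q-values over *all* tested SNPs
   (`stats::p.adjust`, method `"BH"`), before any binning.
2. **Peak binning.** Each chromosome is cut into half-open 500 kb bins
   anchored at position 0 and only the lowest-p SNP per bin survives
   (`bin_peaks`). This collapses LD-inflated association peaks — which span
   hundreds of kb in breeding populations — to single tag SNPs. Ties break
   to the lower position, then the lexicographically smaller marker id, so
   results are reproducible from `(chromosome, bin width)` alone. In
   populations with faster LD decay the bin width should be reduced.
3. **Candidates.** Up to three peak SNPs with $q \le 0.1$ for the focal
   trait (fewer if fewer pass; the single lowest-p SNP as a fallback if none
   pass), plus optionally the single most significant peak SNP for a
   secondary trait — flowering time in practice, since flowering shifts
   most agronomic traits. The auxiliary slot is offered only when the focal
   trait is not itself the auxiliary trait, and is dropped if it duplicates
   a primary candidate.
4. **Combination search.** Every non-empty subset of the candidates (at
   most $2^4 - 1 = 15$) is fitted by OLS on the training data only, scored
   by the Pearson correlation of fitted values with the training phenotype,
   and the best subset wins. Ties prefer fewer markers, then the lower mean
   q-value — parsimony first, because in-sample correlation never decreases
   with added columns. The mean corrected p-value over the chosen markers
   ("average corrected P-value for the model") is carried into the outputs.

`applicability_score` implements the operating rule distilled from the
method's evaluation: promote fixed effects only when
$-\log_{10}(\min q) \ge 2$; below that, plain RR-BLUP is the safer default.

## Cross-validation design

Breeding panels contain full sibs, half sibs and parent–offspring pairs;
random folds let a line's close relatives sit in the training set and
inflate accuracy. `build_folds` therefore clusters lines by partitioning
around medoids (Euclidean distance on imputed dosages; `cluster::pam`),
picks the cluster count maximizing average silhouette width (ties to the
smaller k), and assigns *whole clusters* to folds — largest first onto the
currently smallest fold, with equal-size clusters shuffled under the seed.
Close relatives can then never straddle the train/validation boundary. The
default scan covers k = 2..min(150, n−1) coarsely (step 5) with ±4
refinement; the heavy simulation experiments scan `seq(20, 60, 10)` because
the simulated populations contain 55–60 families and the silhouette optimum
sits in that range.

Phenotypes are long-format records keyed by (line, trait, site, year,
season, rep). Within one site × year × season cell, `adjust_phenotypes`
fits `value ~ line + rep` with sum-to-zero rep contrasts and returns the
per-line least-squares means (the plain line mean when reps are absent).
`run_cv` implements the CV1 composition: the validation cell's season data
*may* appear in training — but only through training-fold lines. Two
restrictions keep the audit airtight:

* training and GWAS phenotypes are adjusted using records of training-fold
  lines only, so validation lines do not even influence rep-effect
  estimation;
* the per-fold GWAS kinship is rebuilt from training-fold lines only, and
  fixed-effect markers are re-selected independently per fold.

With several included cells, the training value of a line is the mean of
its within-cell LS-means across cells (the model carries one record per
line). Accuracy is the Pearson correlation between predicted GEBVs and the
validation cell's adjusted phenotypes, averaged over the five folds.

Prediction itself supports two algebraically identical routes — the
kinship conditional mean and the marker-space ridge dual (Woodbury) — and
the test suite holds them to $10^{-6}$ agreement; numerical jitter
($10^{-6}$ on $\lambda$, applied inside solves only) is expressed
identically in both so the equivalence is exact.

The MLR control is deliberately not a GS method: markers are ranked by
single-marker F-tests, OLS models on the top 1..100 markers are fitted, and
the highest training adjusted $R^2$ wins. Adjusted $R^2$ (not raw fit) is
the "best fit" criterion so the largest model does not win trivially.

## The simulator

`simulate_genotypes` builds an elite-breeding-panel caricature: 30 inbred
founders with alternate-allele frequencies uniform on (0.05, 0.5), 55
biparental families, six rounds of selfing from each F1 with Poisson
crossovers (Haldane model, 1.5 expected crossovers per chromosome per
meiosis, no interference), 12 chromosomes of 40 Mb — rice-like numbers.
Residual heterozygosity lands near $2^{-6} \approx 1.6\%$. The default
trait set mirrors the three canonical architectures: a flowering-time-like
trait (3 QTL × 10% PVE + 10% polygenic), a purely polygenic yield-like
trait (30%), and a mixed height-like trait (1 QTL × 10% + 25%).

`simulate_phenotypes` normalizes phenotypic variance to 1 per cell so PVE
fractions read directly as heritability shares: each large QTL's effect is
scaled to its exact per-environment PVE, the polygenic component spreads
exchangeable normal effects over all remaining markers, and environments
receive correlated effect vectors per the trait's genetic correlation
matrix (for QTL, cross-environment dependence enters through the sign of
the correlated draw; magnitudes stay pinned to the PVE target).
Unbalancedness is produced by masking whole line × cell blocks — the way
real multi-environment trials lose data to typhoons and pests — rather
than sporadic plots.

What the simulator does *not* emulate: coalescent-realistic LD decay,
selection during line development, epistasis, and dominance. Passing tests
therefore demonstrate correctness of the machinery and the expected
*qualitative* behavior of the methods (fixed-effect benefit under major
QTL, marker-density saturation, GxE composition effects), not calibrated
accuracy forecasts for any particular crop.

## Numerical and design choices

* **Dosage coding** counts the alternate allele; heterozygotes are retained
  (inbred lines are mostly 0/2, but the format does not forbid 1s).
  Positions are 1-based; bins are half-open in bp.
* **Imputation** is per-marker mean, applied after filtering and only where
  a downstream step needs complete data. Marker means are the convention
  that keeps the kinship centering consistent; no model-based imputation is
  attempted.
* **Monomorphism** is judged on observed calls only; markers monomorphic
  within a line subset are skipped (and counted) per GWAS run.
* **Distributed marker subsetting** allocates bins of equal bp width per
  chromosome by largest-remainder rounding of the chromosome's length
  share, then takes the marker nearest each bin midpoint (ties to the lower
  position).
* **G is unshrunk**; the $10^{-6}$ ridge appears only inside linear solves,
  never in stored matrices.
* **$-\log$ means $-\log_{10}$** throughout.
* Every stochastic entry point takes an explicit integer seed and restores
  the caller's RNG stream; rerunning a configuration reproduces results
  byte-identically.

## Problem sizes in the shipped experiments

The acceptance layer runs: dual-formulation agreement at n = 60, m = 300
(10 seeds); REML-vs-grid toys at n = 6 (20 cases); BH equality on 100
random p-vectors of length 1000; GWAS null calibration at n = 100, m = 500
and QTL power at n = 200, m = 1000 (20 seeds); heritability recovery at
n = 300, m = 2000 (targets 0.2/0.4/0.6, 20 replicates each); method
ordering at n = 300, m = 3000 with 5-fold cluster CV (20 replicates per
architecture); marker-subset comparisons at m = 10000 (10 replicates); and
the two-group GxE composition experiment at m = 1500 (10 replicates).
These sizes were chosen so the whole battery runs on a laptop-class single
core while leaving the qualitative contrasts far from their decision
boundaries.

## Known limitations

* **The fallback fixed effect can hurt purely polygenic traits.** When no
  SNP passes FDR, the method still promotes the study-wide lowest-p SNP.
  That SNP is the extreme order statistic of thousands of tests; its
  coefficient is selection-inflated (winner's curse), it is fitted unshrunk,
  and on traits with no mappable QTL it adds pure noise to every GEBV. In
  our polygenic simulations this costs roughly 0.04–0.08 correlation
  relative to plain RR-BLUP — which is exactly why the applicability rule
  ($-\log_{10} q \ge 2$) exists and why the model should not be deployed on
  traits whose GWAS shows nothing.
* One random effect: no explicit GxE covariance, no spatial/AR1 residuals,
  no multi-trait modeling. Multi-environment structure is handled through
  training-set composition, not through the covariance model.
* The GWAS exposes covariates but defaults to intercept-only; population
  structure beyond what kinship absorbs (e.g. subpopulation outliers)
  should be removed upstream — a user-supplied drop list is the supported
  hook.
* CV1 is the only composition scheme; alternative leave-future-out schemes
  are out of scope.
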