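# gsdenovo

Genomic selection for inbred breeding populations with **de novo
GWAS-derived fixed-effect markers**: a cross-validated pipeline that runs a
mixed-model GWAS on each training fold, promotes up to four clearly
associated SNPs to fixed effects, and fits an RR-BLUP model in which those
SNPs are excluded from the genomic relationship matrix. For whom: breeders
and quantitative geneticists who want GBLUP-class prediction that does not
dilute the signal of medium/large-effect QTL, plus the machinery to
evaluate it honestly (family-aware cross-validation, multi-environment
training-set composition, and a breeding-population simulator).

## The model

Prediction uses the linear mixed model

y = Xβ + Zu + e,  u ~ N(0, G σ²ᵤ),  e ~ N(0, I σ²ₑ)

where X contains an intercept plus the raw allele dosages (0/1/2) of the
selected fixed-effect SNPs, and G is the VanRaden method-1 relationship
matrix G = WW′ / (2Σⱼ pⱼ(1−pⱼ)) built from **all markers except the fixed
ones**. With no fixed SNPs this is exactly standard RR-BLUP. Variance
components are estimated by REML through a one-time eigendecomposition of G
and a 1-D search over λ = σ²ₑ/σ²ᵤ.

Fixed-effect SNPs are chosen per cross-validation fold by the four-step
rule: (1) single-marker mixed-model GWAS (Wald tests) on training-fold
lines; (2) Benjamini–Hochberg FDR over all SNPs, then 500 kb peak binning
(lowest-p SNP per bin); (3) up to the three most significant peak SNPs at
FDR ≤ 0.1 for the focal trait (the single lowest-p SNP as fallback if none
pass), plus optionally the top flowering-time SNP; (4) the subset of
candidates maximizing the Pearson correlation of an OLS fit on the training
data is carried into the model. The recommendation rule
−log₁₀(min q) ≥ 2.0 (`applicability_score`) flags when the fixed-effect
model is expected to beat plain RR-BLUP.

## Worked example

```r
library(gsdenovo)

cfg <- sim_config(n_families = 20, lines_per_family = 5, n_markers = 1000,
                  seed = 42,
                  traits = list(trait_spec("flw", n_large_qtl = 2,
                                           pve_per_qtl = 0.15,
                                           polygenic_pve = 0.1, reps = 2)))
sim  <- simulate_genotypes(cfg)          # 100 F6 lines x 1000 SNPs
phe  <- simulate_phenotypes(sim$genotypes, cfg)
cell <- list(site = "S1", year = 2012, season = "dry")

y   <- adjust_phenotypes(phe$phenotypes, cell, "flw")   # per-line LS-means
res <- run_lmm_gwas(sim$genotypes, y, compute_grm(sim$genotypes))
head(res[order(res$p_wald), c("marker_id", "p_wald", "q_fdr")], 3)
#>          marker_id       p_wald        q_fdr
#> 326   chr5_1747913 3.754077e-11 2.290195e-08
#> 770 chr10_20881980 4.683424e-11 2.290195e-08
#> 293  chr4_25807713 7.980729e-07 2.601718e-04

fes <- select_best_combination(select_candidates(bin_peaks(res)),
                               sim$genotypes, y)
fes
#> fixed_effect_set: {chr5_1747913, chr10_20881980, chr4_25807713}
#>   mean q=8.67e-05, training fit r=0.700

folds <- build_folds(sim$genotypes, 5, k_candidates = seq(5, 40, 5), seed = 1)
folds
#> fold_assignment: 100 lines, k=20 clusters (avg silhouette 0.169),
#>   5 folds (sizes 20/20/20/20/20)

comp <- training_composition(as.data.frame(cell), as.data.frame(cell))
for (m in c("rrblup", "rrblup_fe_denovo", "mlr")) {
  cv <- run_cv(sim$genotypes, phe$phenotypes, "flw", comp, m, folds,
               gwas_source = cell, seed = 1)
  cat(m, "mean accuracy:", round(attr(cv, "mean_accuracy"), 3), "\n")
}
#> rrblup mean accuracy: 0.259
#> rrblup_fe_denovo mean accuracy: 0.45
#> mlr mean accuracy: 0.314
```

Two of the three planted QTL are genome-wide significant; the selection
step keeps the three strongest peak SNPs, the silhouette scan recovers the
20 simulated families as clusters, and promoting the GWAS hits to fixed
effects lifts cross-validated accuracy from 0.26 (plain RR-BLUP) to 0.45 —
the behavior the method is designed for on traits with mappable QTL. The
MLR control (top single-regression markers, OLS) sits in between on this
strongly QTL-driven trait.

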