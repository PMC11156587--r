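---
title: "Models and design choices in admixdeconv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in admixdeconv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`admixdeconv` decomposes ancestry-associated gene expression in admixed
cohorts into cis-genetic and environmentally mediated components. This
vignette explains the statistical models, the synthetic-data generator that
makes every stage testable against ground truth, and the design choices
made where the methodology was genuinely open. It states no empirical
result beyond what the package's test suite and `scripts/acceptance.R`
themselves compute.

## 1. Ancestry estimation

Global ancestry θ (the African proportion of a genome) is estimated by
supervised maximum likelihood: with reference allele frequencies p_AFR and
p_EUR at ancestry-informative markers, the dosage at marker v is modelled
as Binomial(2, θ·p_AFR,v + (1−θ)·p_EUR,v) and θ maximizes the summed
log-likelihood over markers (golden-section search on [0, 1], tolerance
1e-6, with an explicit boundary check because a bracketing search cannot
land exactly on 0 or 1). This replaces MCMC admixture programs: with known
reference frequencies the estimand is identical and the estimator is
deterministic, so it can be verified against a grid-search oracle. Samples
whose markers are all uninformative (p_AFR = p_EUR) are flagged
unidentifiable and reported at θ = 0.5.

AIM selection applies three filters: absolute frequency difference above
0.5, pairwise r² below 0.1 within each reference population, and a
Hardy–Weinberg exact test P above 0.01 within each population. The pruning
algorithm is greedy in genomic order with a 1-Mb sliding window (the
standard approach; the source methodology does not name its algorithm), and
the HWE test is the exact conditional test without a mid-P correction.

Local ancestry per feature is the mean African posterior over all SNPs in
the feature span padded by 200 kb, averaged over both haplotypes per
sample. Features with no SNP in the window are flagged and dropped rather
than imputed.

## 2. Differential expression and effect standard errors

Per region, each feature's log₂-CPM (pseudo-count 0.5; library size is the
post-filter column sum) is regressed by unweighted OLS on ancestry plus
covariates (sex, age, quality-surrogate columns); the ancestry coefficient
and its standard error feed the shrinkage stage. We deliberately use plain
OLS rather than precision-weighted moderated regression: the multivariate
shrinkage stage is the inferential engine of the pipeline, and the
effect/standard-error contract it needs (SE = σ/√n scaling) is preserved
exactly by OLS. The local-ancestry variant of the model replaces the shared
global-ancestry regressor with each feature's own local-ancestry score.

Expression used for eQTL mapping and prediction is residualized on the
null covariate model (without ancestry) and z-scored per feature.

## 3. Multivariate adaptive shrinkage and the LFSR

Effects across the R regions are modelled as

  β̂ⱼ | βⱼ ~ N(βⱼ, Sⱼ),  βⱼ ~ π₀·δ₀ + Σₖₗ πₖₗ·N(0, ωₗ·Uₖ),

with Sⱼ = diag(seⱼ)·V·diag(seⱼ). V is the correlation of z-scores over
features that look null everywhere (max |z| < 2). The covariance
dictionary contains the canonical matrices (identity, per-region
singletons, equal effects, heterogeneity 0.25/0.5/0.75) and data-driven
matrices from the top principal components of the strong-set z-scores
(rank-1 per PC plus their joint reconstruction), all normalized to unit
maximum diagonal. The "strong set" is operationalized as features passing
BH FDR < 0.05 in at least one region. The scale grid is geometric with
ratio √2 from (min se)²/100 to 4·max(β̂²); the source methodology is silent
on the grid, and these bounds bracket effects from far below the
measurement floor to far above the largest observation. Likelihoods are
computed by Cholesky factorization in log space (no underflow for |z| up
to 40; verified by the posterior-limit tests).

EM updates only the mixture weights (the standard empirical-Bayes scheme);
a Dirichlet penalty of 10 on the null keeps the null weight conservative.
The penalized log-likelihood trace is returned and is non-decreasing, which
the tests assert on every seeded run. The model is fit in effect space
(EE mode); an exchangeable-z mode is not provided. A random-subset two-pass
scheme (`subset_frac`) mirrors large-scale practice: weights are learned on
a subset and posteriors computed for all features.

Posterior summaries follow the conjugate algebra per component — mean
Uₘ(Uₘ+Sⱼ)⁻¹β̂ⱼ, covariance Uₘ − Uₘ(Uₘ+Sⱼ)⁻¹Uₘ — mixed by responsibilities;
the null contributes a point mass at zero. The local false sign rate is
LFSR = min{P(β ≤ 0 | data), P(β ≥ 0 | data)} with the point mass counted in
both tails, so that π₀ = 1 gives LFSR = 1 and a symmetric prior at β̂ = 0
gives exactly 1/2. The test suite verifies the posterior against dense
two-dimensional Bayes-rule quadrature (tolerance 1e-4 on the posterior
mean) and LFSR conservativeness on fully null simulations.

## 4. cis-eQTL mapping

Nominal mapping regresses residualized expression on dosage plus
covariates within ±500 kb of the TSS (annotated start on +, end on −
strand) at MAF ≥ 0.01, reporting two-sided t-tests computed by the
Frisch–Waugh decomposition so they agree with full OLS to machine
precision. Interaction mapping adds ancestry and dosage×ancestry terms
(MAF ≥ 0.05) and reports the product term; population-stratification
covariates are omitted there, since the interaction is the quantity of
interest. Permutation top associations use a fixed count (default 1,000)
of phenotype permutations rather than an adaptive/beta-approximation
scheme — exactly testable at desk scale, with the empirical p on the grid
k/(P+1). Per-feature multiple testing uses Bonferroni over window
variants; across features we provide Storey q-values with π₀ estimated at
λ = 0.5. Conditional (secondary-signal) mapping is out of scope.

## 5. The elastic-net prediction stage

Expression is imputed from cis dosages (MAF ≥ 0.01, HWE P ≥ 1e-5) with a
coordinate-descent elastic net (covariance updates, compiled) over 20
mixing values α = 0.05…1 and a 100-point geometric λ path spanning four
orders of magnitude below the all-zero λ_max. Cross-model selection and
averaging: each fold's λ is chosen on its held-out split and the final
weights are the mean of the fold models at the best α; predictors are
standardized within training folds only and the weights back-transformed.
`cv_r` is the mean across folds of held-out correlations (per-fold-averaged
rather than concatenated).

Two prediction modes are exposed. The exported weights predict expression
as Σ weightⱼ × dosageⱼ for any samples — this is what the variance
decomposition below uses, matching how such analyses impute within the
study cohort. `cv_pred` additionally returns cross-fitted predictions
(each sample predicted by the fold model that never saw it). The
difference matters when predicted and observed effects come from the same
cohort: averaged-weight predictions share the cohort's realized
cis-genetic signal with the observed effects, which keeps the
variance-explained estimate centered on the realized genetic share, while
cross-fitted predictions remove all data reuse but are markedly noisier at
a few hundred features. The package reports the averaged-weight estimate
and exposes `cv_pred` for sensitivity analyses.

The genetic share itself is `ancestry_effect_variance_explained()`: the
same ancestry model is fit to predicted expression, and r² is the squared
correlation between predicted and observed (posterior-mean) ancestry
effects over ancestry-associated genes with an eQTL.

## 6. Methylation, VMRs and ΔP_ST

CpGs with more than 5 reads in more than 80% of samples are retained and
smoothed by a coverage-weighted triangular rolling mean over 1,000 bp — a
desk-scale replacement for local-likelihood smoothing that preserves the
locally-smoothed-proportion contract. Variable-CpG selection residualizes
smoothed proportions on global ancestry (preserving ancestry-driven
variation downstream), computes PCs of the residuals, re-residualizes on
the top 5 PCs and ranks by residual standard deviation; the top 1% are
merged into VMRs (gap ≤ 1,000 bp, more than 5 CpGs; the merge parameters
are our choice since the reference region-finder's are unpublished). The
per-sample VMR level is summed methylated over summed total reads. On the
compressed simulated genome, the fraction of genuinely variable CpGs is
set by the generator (cluster CpGs over all CpGs), so pipeline runs on
simulated data select that fraction rather than the genome-scale 1%.

P_ST is the partial coefficient of determination of ancestry:
(SSE_reduced − SSE_full)/SSE_reduced, where the full model adds ancestry
to the covariates. For the VMR-adjusted statistic both models additionally
include the gene's VMR levels residualized on local ancestry, age, sex and
the top five methylation PCs, and ΔP_ST = (P_ST − P_ST,VMR)/P_ST. ΔP_ST
may be negative when adjustment increases the ancestry signal; such values
are reported as-is. VMRs are annotated to genes by overlap with the gene
body ± 5 kb.

ΔP_ST is a *downward-biased* estimator of the environmental share, with
three multiplicative attenuation factors that the simulated ground truth
makes explicit. (i) P_ST is a ratio of partial R² statistics whose
numerators carry an O(1/n) inflation; at n ≈ 150 and typical ancestry
partial R² of 0.05–0.15 this costs about a quarter of the signal even with
the true environmental factor as the covariate. (ii) The prescribed
residualization of VMR levels on local ancestry removes a fraction
var(θ)/(var(θ) + θ(1−θ)/2) ≈ 0.17 of the proxy's ancestry-correlated
component — the very component whose removal from expression ΔP_ST
measures. (iii) Proxy measurement noise attenuates the removal roughly in
proportion to the VMR residual's reliability as a readout of the
environmental factor (≈ 0.8 under the generator's read-depth and batch
settings). A small positive offset of about ρ²(E, θ) (~0.02 at the default
ρ = 0.15) partially compensates. The product puts the recovered mean ΔP_ST
near half to two-thirds of the true share under the default study
conditions; `scripts/acceptance.R` computes the realized value, and the
acceptance check of full recovery (0.15 ± 0.05) is expected to fail for
this reason — a property of the estimator, not a defect of the
implementation. The same attenuations apply, unquantifiably, to analyses
of real cohorts.

## 7. The synthetic cohort generator

The generator is first-class, tested code; its defaults are the study
conditions everything else is evaluated under.

**Genotypes.** Global African ancestry is Beta(7.9, 2.1) (mean 0.79,
matching an admixed African-American cohort with mean European ancestry
0.21). Each haplotype is tiled by a Markovian tract process with switch
rate 1e-6 per bp (a desk-scale compression giving ~50 tracts per 50-Mb
haplotype); tract segments are recorded at every switch event so the mean
segment length is exactly the reciprocal rate, and the recorded truth θ is
the realized length-weighted African fraction. Alleles are Bernoulli draws
from the tract-origin frequency. Panel divergence is realistic: the bulk
of variants have small frequency differences (0.5·Beta(1,12)) and 5% are
strongly divergent (|δ| uniform on 0.3–0.6, drawn with headroom so the
intended divergence is never clipped at the frequency bounds). This
matters: if most variants were strongly divergent, the cis window would
collectively tag global ancestry almost perfectly and genotype-predicted
expression would absorb direct and environmental ancestry effects too.

**Expression.** Latent log₂ expression is baseline + b_gen·dosage(causal)
+ b_env·E + b_dir·θ + covariate effects + N(0, 0.4), with per-feature
total ancestry slopes S ~ N(0, 1.25²) correlated 0.8 across the four
regions. The decomposition is defined on the variance (partial-R²) scale:
the environmental slope component is αS with α = 1 − √(1 − env_fraction),
so removing it changes the ancestry-explained variance by exactly
env_fraction; the genetic component is (1−α)wS with w Gaussian such that
cor²(genetic, total) = genetic_fraction. Three quantities are realized
exactly in-sample rather than only in expectation — the ancestry–E
correlation, and the first two weighted moments of w (weights S²,
deviations bounded at ±3σ) — because at n≈150 and J≈200 their sampling
noise would otherwise move the cohort's true shares by more than the
recovery tolerances; the generator defines the study conditions, so the
conditions are made to hold in the data actually generated. Genes whose
window has no variant above the divergence floor carry no genetically
mediated effect (w = 0). Counts are negative binomial with fixed
log-normal per-feature dispersion under a compositional read model
(library reads distributed over features by latent abundance, no feature
above 5% of a library) — without the ceiling, occasional extreme
genotype-effect draws produced single features holding most of a library
and corrupted CPM normalization for every other feature.

**Methylation.** CpGs come in 12-CpG clusters near each TSS plus
background CpGs. Biology acts on the logit scale: a per-cluster
local-ancestry loading, and the environmental factor E loading (0.5) on
the clusters of environmentally responsive features only (half of
features by default). Sparse loading is both mechanistically sensible —
an exposure acts at specific regulatory loci, and exactly those genes
carry an environmentally mediated expression effect — and keeps E's total
variance footprint well below each batch factor's so the PC adjustment
does not absorb it. Batch is modelled as five dense latent factors additive on
the *proportion* scale with cluster-coherent loadings (sd 0.1) — the
measurement-artefact interpretation (conversion-efficiency-like) — so that
the top-5-PC adjustment, which is linear, removes it exactly. Modelling
batch on the logit scale at the magnitude needed to dominate the PCA
ordering leaves logistic-curvature residue after linear PC removal that
swamps the environmental proxy; the variance budget here keeps the proxy's
reliability λ²/(λ² + read noise + residue) around 0.8 at depth 30. Read
depth is Poisson(30) and methylated counts are binomial.

**What passing tests do and do not show.** The generator emulates
two-population divergence, Markovian tracts, shared-but-heterogeneous
regional effects, an ancestry-correlated environment and batch-structured
methylation. It does not emulate LD panels or phasing, isoform structure,
RNA-degradation gradients, multiple environmental factors, or an
environment that leaks into the methylation PCs — in real data a pervasive
exposure could be partially removed by the PC adjustment, biasing ΔP_ST
toward zero in a way these tests cannot detect.

## 8. Numerical choices and degenerate inputs

- Golden-section tolerance 1e-6 with explicit boundary polish for θ̂.
- Mixture likelihoods via Cholesky with log-sum-exp; singular Uₘ + Sⱼ gets
  a 1e-10 ridge.
- EM stops when the penalized log-likelihood gains less than 1e-6 (500
  iteration cap, flagged if hit).
- Coordinate descent skips predictors that are constant within a training
  fold (zero Gram diagonal) instead of dividing by zero.
- Zero-variance features are dropped with warnings in residualization and
  CpG selection (sd below 1e-10 counts as zero).
- All-zero samples give NA TPM columns with a warning; empty filter
  results raise an error naming the thresholds.
- Fisher's exact p sums hypergeometric terms with probability at most
  (1 + 1e-7) times the observed, the standard two-sided convention.
- Rank-sum comparisons use the exact distribution up to 20 untied
  observations and the tie-corrected normal approximation otherwise; fully
  tied inputs return p = 0.5 flagged degenerate.
- Every stochastic function requires an explicit seed; pipeline stages
  derive their seeds from the single run seed, and identical configurations
  reproduce byte-identical outputs.

## 9. Problem sizes used by the tests

The packaged checks run at: 1,634 AIMs × 1,000 samples (ancestry
recovery); 5,000 features × 2–4 regions (mixture recovery and LFSR
calibration); 200 features × 150 samples × 4 regions with 4,000 variants
on a 50-Mb chromosome (genetic- and environmental-fraction recovery);
500 null features × 200 permutations (permutation calibration); and
exhaustive enumeration for universes up to 60 genes (enrichment). These
sizes keep the full suite within a desk-scale compute budget while leaving
each recovery target's sampling error well inside its stated tolerance.

## 10. Known limitations

- The supervised ancestry estimator requires reference allele frequencies;
  it does not perform unsupervised admixture inference and handles exactly
  two ancestral populations.
- Only the effect-space (EE) shrinkage mode is implemented.
- ΔP_ST is a downward-biased estimator of the environmental share (proxy
  noise, local-ancestry over-correction) with a small upward ρ² offset;
  interpret its scale, not its third digit.
- The elastic-net r² mixes realized cis-genetic signal into both axes when
  prediction and observation come from one cohort; `cv_pred` quantifies
  the data-reuse-free alternative.
- Tract posteriors are emitted as hard 0/1 calls (optionally blurred);
  downstream analyses only average them, so posterior sharpness is not
  modelled.
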