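---
title: "Models and methods for infant hormone twin-cohort analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for infant hormone twin-cohort analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minitwin)
```

minitwin analyses a hormone phenotype (salivary testosterone, pg/ml)
measured in an infant cohort that mixes twin pairs and singletons, together
with demographic/medical covariates, a salivary blood-contamination marker
(transferrin, mg/dl), and a candidate-gene SNP panel. This vignette is the
package's own account of the models it fits, the choices it makes where the
design was genuinely open, and what its simulation-based tests do and do
not establish.

## The family-clustered mixed model

Twins are repeated measures of their family. Every association stage uses

$$y = X\beta + u_{\text{fam}} + e,\qquad
  u_{\text{fam}}\sim N(0,\sigma^2_{f}),\quad e\sim N(0,\sigma^2_{e}),$$

fit by maximum likelihood (ML, not REML: the likelihood-ratio tests
downstream compare fixed-effect specifications). Writing
$\theta=\sigma^2_f/\sigma^2_e$, both $\beta$ and $\sigma^2_e$ profile out
in closed form for the family block structure, leaving a one-dimensional
likelihood in $\theta$ that is maximized by golden-section search on
$\log\theta \in [-15, 15]$; the boundary $\theta = 0$ is always evaluated
and wins ties (within $10^{-7}$ log-likelihood units), so uninformative
clustering degrades exactly to OLS. The tests cross-check coefficients,
likelihood and variance components against `lme4::lmer` to $10^{-6}$.

Wald p-values use the normal reference; with a few hundred observations
and one variance ratio this is the standard asymptotic choice.

## Adaptive-Lasso covariate selection

The environmental stage selects among 16 demographic/medical covariates
(categoricals expanded to reference-coded indicators, an explicit
`Missing` income level kept as a level; the expanded count is recorded in
`standardize_and_center()$n_predictors` rather than asserted) while always
keeping log10 transferrin and age. The procedure:

1. **FGLS initial estimator** — OLS, then method-of-moments variance
   estimates from within-family residual cross-products (a negative family
   variance truncates to 0 and is flagged), then one GLS step.
2. **Whitening** — multiply $y$ and $X$ block-wise by
   $(I+\hat\theta J)^{-1/2}$, leaving homoscedastic, uncorrelated errors
   up to the overall scale, which BIC ranking ignores.
3. **Weighted Lasso** — coordinate descent (tolerance $10^{-8}$ on the
   maximum coefficient change, warm starts) over 100 log-spaced penalties
   from $\lambda_{\max}$ (smallest penalty zeroing every penalized
   coefficient) down to $10^{-4}\lambda_{\max}$, with weights
   $w_j = 1/|\hat\beta^{\text{init}}_j|^{\gamma}$ and $w_j=0$ on the
   always-in block. An initial coefficient that is numerically zero gets a
   capped weight ($10^8$) so the covariate can still enter.
4. **BIC tuning** — $\mathrm{BIC}(\lambda) = n\log(\mathrm{RSS}/n) +
   \mathrm{df}\,\log n$ with df the nonzero count and $n$ the number of
   individuals (the simplest defensible sample-size convention under
   clustering; the clusters are small and numerous, so $\log n$ and
   $\log n_{\text{fam}}$ differ by a near-constant that rarely moves the
   argmin). Ties resolve toward the larger penalty.

**Why γ = 2.** The weight exponent is the one genuinely open parameter.
With γ = 1, a null covariate whose sample association happens to reach
|z| ≈ 2.6 survives BIC often enough that at cohort scale (n = 220, 29
predictors, one strong true effect) the exact oracle support is recovered
in only ~85% of replicates — the failures are always overselection, never
a missed signal. Quadratic weights push chance associations' entry so far
down the path that BIC rejects them (~99% exact recovery under the same
conditions), while a strong true effect's weight is tiny either way. The
default is therefore `gamma = 2`, exposed as an argument.

**Bootstrap.** Stability is assessed by resampling whole families with
replacement (individual-level resampling would destroy the twin
correlation the model assumes), re-standardizing each resample and
re-running the full selection; replicate *b* uses seed `base_seed + b`.
Degenerate resamples (constant or collinear columns — possible when a rare
indicator concentrates in few families) are skipped and the effective
denominator reported. Note that bootstrap counts resample *one* dataset:
a covariate spuriously associated in that dataset is re-selected
persistently, so null counts approaching B/2 for one covariate are a
feature of the data, not a calibration failure; the package's null
calibration test therefore pools counts over independent datasets.

**Post-selection inference.** The unpenalized mixed model is refit on the
support; predictors are flagged at α/m with m the *full*-model predictor
count (0.05/29 ≈ 0.0017 at study scale). The per-predictor r² column is
defined — since "r²" has no canonical mixed-model definition — as the
squared semi-partial correlation computed on the whitened regression: the
drop in whitened R² when that predictor is removed. The definition rides
along in the documentation, and R² is the whitened model R².

## Twin resemblance and the ACE decomposition

Intraclass correlations use the one-way ANOVA ICC(1) on complete same-sex
pairs per zygosity–sex group, optionally after OLS covariate adjustment
(both adjusted and raw ICCs are one call apart, since the study convention
is unstated); confidence intervals use the exact-F method at 95%. Groups
with fewer than two pairs report `NA`, never a zero.

The ACE model gives each pair covariance $k\sigma^2_A+\sigma^2_C$
($k=1$ MZ, $0.5$ DZ) and each individual variance
$\sigma^2_A+\sigma^2_C+\sigma^2_E$. Because the 2×2 pair covariance is
constant within a zygosity group, the Gaussian likelihood reduces to
group-level sufficient statistics and each evaluation is $O(p^2)$ — which
is what makes the 10,000-pair recovery tests cheap. Optimization is
bounded L-BFGS-B ($\sigma^2 \ge 0$) from three deterministic starts (equal
split, E-dominant, C-dominant), best likelihood winning and ties breaking
toward smaller $\sigma^2_A$. Singletons, unpaired twins and opposite-sex
co-twins (in sex-stratified runs) enter as size-one families: they inform
the fixed effects and the total variance.

**One-tailed tests at the boundary.** A t reference for a variance
component tested against its boundary is ill-defined, so the one-tailed
p-values are likelihood-ratio tests against the $\sigma^2=0$ null with the
$\tfrac12\chi^2_0+\tfrac12\chi^2_1$ mixture reference ($p=1$ when the
component sits at the boundary); a one-sided Wald z p-value is also
emitted for comparability (NA when the Hessian degenerates at the
boundary).

## SNP panel QC and association

Allele-frequency statistics assume independent genomes, which twins are
not: folded MAF and the Hardy–Weinberg test are computed on one randomly
chosen member per family (seeded). HWE uses the exact conditional test
(closed-form log-factorial distribution of the heterozygote count given
allele counts) because the χ² approximation is unusable at the 1e-8
removal tail with a few hundred founders; the suite checks it against an
independent recurrence-based enumeration for all totals ≤ 200. Filters:
call rate ≥ 0.95, folded MAF ≥ 0.05 (strict `<` removal, so a SNP at
exactly the threshold stays), HWE p ≥ 1e-8. LD pruning is a greedy
left-to-right window scan (defaults window 50, step 5, r² 0.2 —
config-exposed, since the study's pruning parameters are unstated).
Missing dosages are mean-imputed for PCA and LD pruning only; association
tests instead drop missing individuals per SNP (`n_used` is recorded).

Genotype PCs are fit by SVD of column-standardized dosages on the
one-per-family subset and projected for everyone; each loading is oriented
so its largest-magnitude entry is positive, making outputs reproducible.
The sensitivity-subset scans reuse the full-panel PCs (ancestry does not
change with the subset) and drop the transferrin covariate, which defines
the subset.

Each SNP's test is `2*(loglik_full - loglik_null)` against $\chi^2_1$ (no
boundary issue: the SNP effect is a fixed effect); tiny negative LR values
from finite optimizer tolerance clip to 0. A dosage numerically collinear
with the null design returns lr = 0, p = 1 rather than an error, and
monomorphic SNPs are skipped with a reason — a scan never aborts.
Benjamini–Hochberg adjustment is delegated to `stats::p.adjust` and
checked against the step-up definition.

## Power simulation

Each replicate simulates genotypes and an ACE phenotype on the default
cohort structure (27 MZ, 27+2 DZ pairs, 2 unpaired twins, 108 singletons,
n = 222), adds the per-allele effect, and tests at α = 0.05/500. The
generative variance components default to the male-scale estimates
(a² = 0, c² = 0.627 of a 13.4 pg/ml SD). Within a MAF row all effect
sizes share replicate seeds (common random numbers), so estimated power is
monotone in effect size by construction and the monotonicity test is
exact rather than statistical; rows use disjoint seed ranges. Nuisance
covariates are off by default (the power model is the marginal SNP test);
a flag adds the transferrin covariate to both the generator and the
fitted models. The desk default is 1,000 replicates per cell; the full
10,000-replicate setting is one argument.

## Random-forest stability selection

Forests need independent rows, so one twin per complete pair is kept
(seeded choice). Both the response and every SNP dosage are residualized
by OLS on the covariates and PCs before the forest sees them — this stops
strong covariates masking weak genetic signal, and makes the dosages
continuous features. Importance is permutation importance (mean OOB MSE
increase) rather than impurity: standard for regression screening and
less biased under correlated predictors; the study's measure is unstated.
Defaults: ntree = 2000, mtry = ⌈p/3⌉ (all fractional rules round up),
minimum node size 5, 50 runs with seeds `base_seed + run`, per-run top-30
lists with ties broken by panel order, and the across-run intersection as
the stable set. The forests themselves come from `ranger` (single-thread,
seeded, hence deterministic); the stability logic is the package's.

## The synthetic cohort generator

The generator emulates the study conditions, and its defaults are fixed:
222 infants (27 MZ pairs, 27 same-sex DZ pairs, 2 opposite-sex DZ pairs, 2
unpaired twins, 108 singletons; male share 119/222); phenotype mean
40 pg/ml with a² = 0, c² = 0.627, e² = 0.373 on a ~13.4 pg/ml SD;
log-normal transferrin (meanlog −0.45, sdlog 0.8: mean ≈ 0.88 mg/dl,
right-skewed, ~38% below the 0.50 mg/dl sensitivity cutoff); ages in
[2.70, 4.80] months shared within a pair (one home visit); APGAR integer
concentrated in 7–10 (mean ≈ 8.7); Table-1-style categorical frequencies
with parental/household covariates constant within family. Covariate
effects apply to *centred* covariates so the configured mean stays the
phenotype mean; defaults plant the transferrin association
(17.4 pg/ml per log10 unit) and a male-only APGAR effect (−5.3 pg/ml per
point). The correlation between transferrin and phenotype is a knob
(`beta_cov`), deliberately agnostic about whether it reflects blood
contamination or biology.

DZ genotypes come from explicit parental-gamete simulation — two HWE
parents, one transmitted allele each — which guarantees valid {0,1,2}
dosages and expected within-pair dosage correlation 0.5 exactly; MZ
co-twins share a row; singletons are HWE draws. Additive-genetic phenotype
deviates are bivariate normal per pair with the zygosity correlation,
matching the ACE likelihood fit downstream. Detection-limit coding
(values < 1 pg/ml → 0) applies after noise, mirroring assay behaviour.

**What passing tests do not show.** The generator draws covariates
independently of genotypes and (except through the planted effects) of
each other; real cohorts have confounding, ancestry-correlated covariates,
assay heteroscedasticity and genuinely non-normal phenotypes. Recovery and
calibration results on this testbed validate the estimators under their
own assumptions — they do not certify behaviour under model
misspecification.

## Numerical choices and problem sizes

Simulation scales in the test suite are chosen to give each check real
statistical teeth at desk runtimes: twin-correlation and DZ-transmission
checks at 10,000 pairs (tolerances ±0.02–0.03), ACE recovery at
5,000 + 5,000 pairs × 100 replicates, LRT size at α = 1e-4 over 50,000
null replicates on a reduced 100-infant structure (25 pairs + 50
singletons), Lasso oracle recovery over 200 replicates at n = 220 with 29
predictors, RF stability at 50 runs × 500 trees on a 200 × 100 panel with
a planted SNP explaining 30% of residual variance. Every stochastic
routine takes an explicit seed; derived seeds are additive offsets.

Known limitations: no sex-limitation or ADE twin models; no kinship beyond
declared zygosity (association uses only the family intercept); no
imputation-dosage uncertainty; the power study has no analytic
approximation — it is Monte-Carlo only.
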