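---
title: "Cross-trait genetic architecture from summary statistics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-trait genetic architecture from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldscreg)
```

This vignette documents the statistical models behind `ldscreg`, the
assumptions they make, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, and the
numerical choices made where the design was genuinely open.

## 1. The polygenic regression model

For a quantitative trait measured in $N_j$ individuals at SNP $j$, with
standardized effect convention $\beta_j = z_j / \sqrt{N_j}$, the
polygenic model with per-SNP causal variance $h^2_g / M$ implies

$$E[\chi^2_j] \;\approx\; \frac{N_j\, h^2_g}{M}\, l_j + 1,
\qquad l_j = \sum_k r^2(j,k),$$

where the LD score $l_j$ sums squared correlations over SNPs within a
window of $j$ (1 Mb radius by default, a common 1 cM surrogate), and the
intercept absorbs confounding inflation (population stratification,
cryptic relatedness).  `estimate_h2()` fits this by weighted least
squares of $\chi^2_j$ on $N_j l_j / M$ with a **free** intercept: the
"+1" is the null value, but real analyses must allow it to move.

Assumptions worth keeping in mind:

* *Polygenicity.*  The regression attributes signal through the linear
  relation between $\chi^2$ and $l$.  Outlying hits violate it, so SNPs
  with $\chi^2$ above `chisq_max` (default $\max(80,\,0.001\,\bar N)$,
  the convention of the standard LD score software) are excluded from
  the regression — not from clumping or locus attribution.
* *Effect sizes independent of LD.*  When causal variants
  systematically sit in high- or low-LD positions, the single-component
  slope is biased; the stratified model (Section 6) is the remedy.
* *A matching LD reference.*  LD scores must come from a panel whose
  correlation structure matches the study population.

**Weights.**  Two corrections are combined into
$w_j = 1/[\max(l_j, 1)\,(1 + N h^2 l_j/M)^2]$: the $1/l_j$ term
counters over-counting of correlated SNPs, the squared term counters the
heteroscedasticity of $\chi^2_j$ (whose variance is twice its squared
expectation).  Since the weights depend on the unknown $h^2$, the fit
starts unweighted and re-weights twice (`n_iter = 2`); further
iterations change estimates negligibly.

**Standard errors.**  A delete-one-block jackknife over `n_blocks`
contiguous equal-SNP-count blocks (default 200, the genome-scale
default of the cited software; the packaged simulation studies use 100
blocks aligned with the panel's 100 independent LD blocks, matching the
jackknife's independence assumption).  The jackknife is mildly
anti-conservative when a few high-LD blocks dominate the regression
leverage — the packaged calibration study checks that 95% intervals
cover the truth in 90–99 of 100 replicates, and it sits in the lower
half of that band.

## 2. Liability scale

Case-control heritability estimated on the observed 0/1 scale is
converted with

$$h^2_{liab} = h^2_{obs}\,
  \frac{F(1-F)}{\varphi(\Phi^{-1}(F))^2}\,\frac{F(1-F)}{P(1-P)},$$

where $P$ is the sample and $F$ the population prevalence.  At
$P = F = 1/2$ the factor is exactly $\pi/2$.  The conversion multiplies
the estimate, its SE and every jackknife delete value, so downstream
ratio statistics remain coherent.  Prevalences are configuration inputs;
they are not estimable from summary statistics.

## 3. Locus exclusion and attribution

`clump_loci()` implements greedy clumping: repeatedly take the most
significant remaining SNP with $p < 5\times10^{-8}$, emit its
$\pm 500$ kb window, and drop everything inside.  `proportion_explained()`
compares the heritability estimate with and without the clumped regions:
$1 - \hat h^2_{excl}/\hat h^2_{full}$.  Two choices matter:

* **The denominator $M$ is kept at its full-analysis value** after
  exclusion.  The quotient then reflects heritability removed with the
  loci rather than a change of denominator; conveniently, it also means
  the unexcluded polygenic background contributes the same slope before
  and after, so the expected proportion equals the heritability share
  of the excluded loci themselves.
* Attribution through an LD-score slope is *unbiased only on average
  over locus positions*: a single concentrated locus is credited
  according to its position's leverage in the $\chi^2$-on-$l$
  regression.  The calibration study therefore randomizes locus
  positions across replicates and compares the ratio of replicate-mean
  estimates (which also avoids the Jensen bias of averaging ratios),
  with loci sized so that their peak $\chi^2$ (~40) is genome-wide
  significant yet below `chisq_max`.

## 4. Cross-trait regression and genetic correlation

For two traits the product regression

$$E[z_{1j} z_{2j}] \;\approx\; \frac{\sqrt{N_1 N_2}\,\rho_g}{M}\, l_j
  + \frac{N_s r}{\sqrt{N_1 N_2}}$$

estimates the genetic covariance $\rho_g$ (slope) and the
sample-overlap term (intercept; $N_s$ overlapping samples with
phenotypic correlation $r$).  Weights mirror the single-trait form with
per-trait heteroscedasticity factors plus the squared expected product,
$w_j^{-1} = \max(l_j,1)\,[(1+N_1h^2_1l_j/M)(1+N_2h^2_2l_j/M) +
(\sqrt{N_1N_2}\rho_g l_j/M + c)^2]$, which reduces to twice the
single-trait weight when the traits coincide — so a trait paired with
itself reproduces the $\chi^2$ regression exactly, and $\hat r_g$ of a
trait with itself is 1 by construction.

$\hat r_g = \hat\rho_g/\sqrt{\hat h^2_1 \hat h^2_2}$ carries a
jackknife SE computed on the **delete-block ratios** (all three
regressions share one block scheme).  $\hat r_g$ is *not* clipped to
$[-1,1]$; out-of-range values are flagged instead, preserving
unbiasedness of downstream meta-analyses.  Differences between two
correlations (e.g. a trait against two disease subtypes) are tested
with a z-statistic whose covariance term comes from the paired delete
values when block schemes match, and is set to zero (with a warning)
otherwise.  Bonferroni thresholds are plain $\alpha/n$:
$0.05/15$ for 15 trait pairs, $0.05/(6\times38)$ for a 6-by-38 screen,
$0.05/1703$ for a 1703-region local scan.

A screen for "traits with a heritable component" is conventionally
applied before correlation analyses; no universal criterion exists, so
the package leaves it to the user (the natural filter is
$\hat h^2/\mathrm{SE} \ge 4$).

## 5. Local genetic covariance

Within a region with LD matrix $R = U\Lambda U'$, truncated at rank
$k$, the estimator is

$$\widehat{cov}_{local} = \frac{z_1' U_k \Lambda_k^{-1} U_k' z_2 -
k\,\hat c}{\sqrt{N_1 N_2}},$$

with $\hat c$ the genome-wide cross-trait intercept, and analogous
local $h^2$ forms subtracting $k$ times the single-trait intercepts.
Genome-wide intercepts are estimated once and reused for every region.

* **Rank truncation.**  Default $k$ keeps eigenvalues covering 99.9% of
  the trace (with near-null directions dropped).  For exact synthetic
  panels this is effectively full rank, which is what makes the sum of
  local $h^2$ over a partition agree with the genome-wide estimate;
  heavy truncation would discard a fixed fraction of every region's
  signal.  With noisy reference panels a user-supplied smaller $k$
  stabilizes $\Lambda^{-1}$; an infeasible $k$ is reduced with a
  warning.
* **Inference.**  The reported SE uses the asymptotic quadratic-form
  variance with plug-in signal terms.  The p-value, however, uses the
  *exact null law* of the bilinear form: in the eigenbasis,
  $z_1'Az_2$ is distributed as $aU - bV$ with $U,V$ iid
  $\chi^2_k$ and $a,b$ determined by the noise scales and their
  correlation — noticeably heavier-tailed than its normal approximation
  at scan-level (Bonferroni) thresholds.  The null scales are floored
  at the genome-wide intercepts but estimated from the region's own
  marginal statistics ($q_{tt}/k$), so polygenic background
  heritability without *excess local sharing* is part of the null
  rather than a source of family-wise false positives.  The package's
  null-scan study verifies family-wise error control at the
  $0.05/n_{regions}$ threshold.

The scan reports covariances, not per-region correlations: normalizing
by local $h^2$ estimates is unstable exactly where local heritability
is small, which is most of the genome.

## 6. Stratified regression and enrichment

With annotation categories $c$ (binary memberships or non-negative
continuous values, always including `base` = all SNPs) and stratified
LD scores $l_{j,c} = \sum_k a_{k,c} r^2(j,k)$,

$$E[\chi^2_j] = N_j \sum_c \tau_c\, l_{j,c} + 1 .$$

Per-SNP modelled variance is $v_j = \sum_c a_{j,c}\tau_c$; a category's
share of heritability is $\sum_{j\in C} v_j / \sum_j v_j$ and its
enrichment is that share over its SNP share.  Implementation choices:

* Weights and jackknife blocks are inherited from the total-LD fit, so
  a base-only model reproduces `estimate_h2()` *exactly*.
* An exact disjoint covering of the SNPs spans the base column; the
  redundant base is then dropped from the regression (with a message)
  and shares are computed from the partition — this is what makes
  partition shares sum to one.  Any other collinearity is an error
  naming the offending columns.
* Continuous-valued columns (e.g. MAF-bin adjusters from
  `maf_bin_annotations()`) enter the regression but are excluded from
  enrichment reporting, which is defined only for memberships.
* Negative category heritability estimates are allowed (the regression
  estimator is unbiased; truncation would bias meta-analyses) and
  flagged with a message.

`cell_type_scan()` adds candidate annotations one at a time to the
baseline model — one refit per candidate, mirroring scans over
cell-type-specific histone-mark tracks — and applies
$\alpha/n_{candidates}$.  `meta_analyze()` pools one category across
traits by DerSimonian–Laird random effects (delegated to
`metafor::rma.uni(method = "DL")`); the packaged tests pin the
implementation to hand-computed DL arithmetic.  Enrichment is the
default pooled quantity; proportion-of-$h^2$ pooling is available via
`field = "prop_h2"`.

## 7. Directional screening

Given SNP sets ascertained separately on traits X and Y (LD-pruned
genome-wide significant SNPs via `select_pruned()`, or lead SNPs of
blocks with posterior probability of association $\ge 0.9$ via
`block_ppa()`, which combines Wakefield Bayes factors with an
empirical-Bayes EM estimate of the block prior), four Gaussian
measurement-error models are compared on the observed standardized
effect pairs.  Each X-ascertained SNP contributes the density of its
effect on Y and vice versa, so all four likelihoods cover the same data
components:

* **Causal X→Y**: X-ascertained SNPs transmit with one free slope
  ($\beta_y \sim N(\alpha\beta_x,\ se_y^2+\alpha^2se_x^2)$);
  Y-ascertained SNPs act on Y independently of X
  ($\beta_x \sim N(0, se_x^2)$).  **Causal Y→X** is the mirror image.
* **Independent**: no cross-trait relation in either set.
* **Shared factor (non-causal pleiotropy)**: one latent factor drives
  both traits, forcing the *same* effect ratio $\lambda$ in both sets.

The shared-factor form is the deliberate choice here: a "pleiotropy"
model with two unrelated free slopes would nest both causal models, so
the relative likelihood ratio
$LR = \max L(\text{non-causal})/\max L(\text{causal})$ could never fall
below 1 and the decision rule $LR < 0.05$ could never fire.  With the
shared-factor form, genuinely directional data (proportional
transmitted effects among X-ascertained SNPs, trait-specific effects
among Y-ascertained ones) discredit every non-causal model, while
shared-factor data (one ratio in both sets) defeat the causal ones.
Conversely, because independence *is* nested in each causal model (at
slope zero), $LR \le 1$ always; under independence it hovers near 1 and
verdicts remain "none".

A verdict additionally requires no evidence of set-dependent
transmission slopes: the slope of downstream-on-upstream effects is
estimated separately in the two sets (weighted through-origin
regression with HC3 leverage-corrected robust SEs) and compared by a
two-sided t-test at 0.05.  A set without leverage on the upstream
effect — exactly what a trait-specific ascertained set looks like under
true causation — yields a huge slope SE and cannot trigger the flag.
An inestimable slope withholds the verdict.  Slope optimizations are
bounded 1-D searches (`optimize` on $[-50, 50]$; the shared ratio is
searched on both sign branches since $\lambda = 0$ is a likelihood
singularity).

Defaults left open by convention and fixed here: Wakefield prior
variance $W = 0.04$ on the standardized-effect scale, pruning
$r^2_{max} = 0.1$, PPA cutoff 0.9, LR threshold 0.05 with no
multiple-testing correction (the decision rule is used as stated).

## 8. The synthetic-data generator

`simulate_sumstats_pair()` generates Z-scores directly at the summary
level — no individual genotypes — which matches the asymptotic model
the estimators assume and keeps runtimes at desk scale:

* **LD**: independent blocks (default 100 blocks of 200 SNPs,
  $M = 20{,}000$) with AR(1) within-block correlation; each block's
  coefficient is drawn uniformly from `ld_rho` (default 0.1–0.8),
  emulating the genome-wide variation of LD strength.  Blocks sit >1 Mb
  apart in synthetic coordinates across the 22 autosomes, so ±500 kb
  windows and the 1 Mb LD-score window behave realistically.
* **Effects**: per-SNP standardized effect pairs are bivariate normal
  with correlation `rg`; per-SNP variances follow annotation
  multipliers (for enrichment scenarios) and sum to each trait's
  observed-scale $h^2$.  Blocks listed in `large_effect_loci`
  concentrate their stated heritability share on one randomly placed
  SNP each (random placement keeps LD-score attribution unbiased over
  replicates; signs couple across traits according to `rg`).
* **Z-scores**: per block $z = \sqrt{N}\,R\alpha + \varepsilon$ with
  $\varepsilon \sim N(0, R)$, and the two studies' noise correlated per
  SNP by $N_s r/\sqrt{N_1N_2}$ — sample overlap enters exactly where
  the cross-trait intercept expects it.
* **Binary traits**: simulated on the observed scale with
  $h^2_{obs} = h^2_{liab}$ divided by the liability factor, so the
  conversion is exactly invertible — a deliberate self-consistency
  device, not a claim about real case-control sampling.
* A truth manifest records every quantity an estimator claims to
  recover (observed/liability $h^2$, $\rho_g$, $r_g$, the overlap
  intercept, per-block heritability, locus positions and shares).

What the generator does **not** emulate: realistic human MAF and LD
spectra, in-sample LD estimation noise (the analysis uses the panel's
exact correlations), linked selection, imputation artefacts, allele
coding errors, or the X chromosome.  Passing calibration tests
therefore demonstrates correctness of the estimators under their own
assumptions, not robustness to real-data violations of them.

Default study sizes in the packaged tests and in
`scripts/acceptance.R`: $M = 20{,}000$ SNPs, 100 blocks,
$N = 50{,}000$ (100,000 for the local-scan power study), 50–100
replicates per recovery study, 100 jackknife blocks aligned with the
LD blocks.  These sizes give Monte-Carlo standard errors comfortably
below the tolerances being checked while keeping the full suite at a
few minutes on one CPU.

## 9. Known limitations

* Per-SNP sample sizes are taken as given; meta-analytic N
  heterogeneity beyond the per-SNP column is not modelled.
* The jackknife slightly understates SEs when few high-LD blocks carry
  most regression leverage (see Section 1).
* Local covariance p-values assume the panel's LD is exact; with noisy
  reference LD the truncation rank should be reduced by the user.
* The directional screen is a coarse model comparison, not a formal
  Mendelian randomization estimator: it assumes Gaussian effects, one
  transmission slope, and clean ascertainment; weak-instrument and
  winner's-curse effects are not corrected.
* Strand-ambiguous (A/T, C/G) SNPs are always removed during
  harmonization; with frequency information one could rescue some, at
  the cost of frequency-mismatch errors.
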