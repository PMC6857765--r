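---
title: "Estimating maternal causal effects on birth weight: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating maternal causal effects on birth weight: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duomr)
```

## The problem

Whether maternal serum lipid concentrations during pregnancy (HDL-C, LDL-C,
triglycerides) causally influence offspring birth weight is hard to settle
observationally. Mendelian randomization (MR) uses SNPs robustly associated
with an exposure as instrumental variables, but the maternal setting has a
specific confounder: mothers transmit half their alleles to their children,
so an association between maternal genotype and offspring birth weight can
run through the *child's* genotype rather than through the intrauterine
environment.

duomr implements a two-sample MR design that addresses this. Sample 1
supplies SNP-lipid associations ($\hat\beta_{ZX}$) from a large lipid GWAS;
sample 2 supplies SNP-birth-weight associations partitioned into a
maternal-specific component $\hat\beta_{ZY}^{(mat)}$ (the intrauterine path,
with fetal genotype held fixed) and a fetal-specific component
$\hat\beta_{ZY}^{(fet)}$. The per-SNP maternal causal estimate is the Wald
ratio $\hat\beta_{ZY}^{(mat)}/\hat\beta_{ZX}$, and instruments are pooled
with the usual two-sample estimators.

## The partition

Biobank-scale cohorts report two marginal associations per SNP: genotype on
*own* birth weight, and (for women) genotype on the *offspring's* birth
weight. Under Mendelian transmission (coefficient $\tfrac12$), random
mating, and no paternal path to the intrauterine environment, their
expectations mix the maternal- and fetal-specific effects:

$$E[\hat\beta_{own}] = \beta_{fet} + \tfrac12\beta_{mat}, \qquad
  E[\hat\beta_{off}] = \beta_{mat} + \tfrac12\beta_{fet}.$$

`partition_effects()` inverts this linear system in closed form,

$$\hat\beta_{mat} = \tfrac{4\hat\beta_{off} - 2\hat\beta_{own}}{3}, \qquad
  \hat\beta_{fet} = \tfrac{4\hat\beta_{own} - 2\hat\beta_{off}}{3},$$

with standard errors by linear error propagation (for independent marginals,
$\mathrm{var}(\hat\beta_{mat}) = \tfrac49 se_{own}^2 + \tfrac{16}9
se_{off}^2$, and a maternal-fetal sampling correlation of $-0.8$ when the
marginal SEs are equal). A user-supplied `overlap_cov` carries the sampling
covariance induced when the two marginal GWAS share individuals; we do not
estimate that covariance (full-likelihood structural equation modelling with
LD-score-based overlap weighting is out of scope), we only propagate it.
The partition is validated against its individual-level oracle,
`conditional_duo_regression()` — the two-covariate regression of offspring
birth weight on maternal and offspring genotype — on simulated duos; the two
agree within joint sampling error and the closed form is exactly unbiased on
a $\pm 0.05$ grid of true effects.

## Estimators

All estimators consume a harmonized, per-exposure-selected, optionally
oriented `instrument_table`.

* **IVW** (`mr_ivw`): inverse-variance weighted mean of the Wald ratios,
  identical (and tested to 1e-12 against a `lm()` oracle) to zero-intercept
  WLS of $\hat\beta_{ZY}$ on $\hat\beta_{ZX}$ with weights $1/se_{ZY}^2$.
* **MR-Egger** (`mr_egger`): same regression with a free intercept; the
  intercept estimates directional pleiotropy, the slope is causal under the
  InSIDE assumption. The table must first pass `orient_positive()` because
  the intercept's sign depends on allele orientation.
* **Weighted median** (`mr_weighted_median`): interpolated weighted median
  of the ratios; consistent while under 50% of weight is invalid.
* **Mode-based** (`mr_mode`): normal-kernel density over the ratios
  (bandwidth `phi` x a modified Silverman rule using min(SD, MAD)); the
  density maximum is the estimate; the weighted variant gives each SNP its
  inverse-variance mass (ZEMPA assumption).
* **Multivariable** (`mv_ivw`, `mv_egger`): joint WLS of
  $\hat\beta_{ZY}^{(mat)}$ on all three lipid beta columns, zero-intercept
  by default; `mv_egger` frees the intercept after orienting on one lipid
  and is run once per lipid of interest.

### Numerical and inferential conventions

* **SEs**: IVW/Egger (and the multivariable fits) use multiplicative
  random effects — the fixed-effect SE times
  $\max(1, \hat\sigma)$ — matching the dominant implementation convention;
  a `random_effects = FALSE` flag gives fixed-effect SEs. Which variant
  produced the published intervals is not documented, so published CI
  *widths* are not a reproduction target; point estimates are.
* **CIs**: normal quantiles for IVW/median/mode; $t_{L-2}$ for the Egger
  slope and intercept.
* **Bootstrap**: median/mode SEs come from parametric resampling of both
  exposure and outcome betas from their sampling distributions; `n_boot`
  defaults to 1000 and a seed is mandatory, so results are exactly
  reproducible.
* **Degenerate inputs**: zero exposure betas are excluded from ratios (and
  dropped at orientation, where their sign is undefined); identical ratios
  give a zero kernel bandwidth, in which case the mode returns the common
  ratio with a precision-weighted SE; IVW refuses fewer than 2 SNPs, the
  others fewer than 3.
* **Tie-breaks**: the weighted median interpolates cumulative-weight
  midpoints with `ties = "ordered"`; the mode takes the grid argmax of a
  1024-point density.

### Instrument selection and harmonization

The unrestricted set keeps SNPs with exposure $P < 5\times10^{-8}$; the
restricted set additionally demands $P > 0.05$ for both other lipids,
isolating single-lipid instruments. Harmonization joins on rsID
(case-insensitive), aligns alleles (flipping outcome betas for swapped
alleles, complementing for strand flips) and handles strand-ambiguous (A/T,
C/G) SNPs by allele frequency, dropping them when the frequency is missing
or within 0.08 of 0.5. The 0.08 window is our choice — the source analyses
do not document their palindrome handling — and is configurable; every
exclusion is logged with a reason code. Instruments are assumed pre-pruned
for LD; no clumping is implemented.

## Diagnostics

`i2_gx()` computes the $I^2_{GX}$ regression-dilution statistic for the
Egger NOME assumption, $\max(0, (Q_{GX} - (L-1))/Q_{GX})$; values near 1
mean exposure-beta measurement error is negligible. The weighting variant
(exposure-variance vs Egger outcome-variance weights) is not documented in
the source analyses, so both are available; unweighted is the default.
`funnel_data()` adds a numerical asymmetry test (precision-weighted
regression of ratio on ratio SE) to the visual funnel, since "no asymmetry"
should be checkable mechanically. `scatter_data()` emits per-SNP points,
per-method fitted lines, and a leave-one-out outlier flag (default: an
IVW shift over 3x the median absolute leave-one-out shift), which is the
mechanism behind outlier-exclusion re-runs (`exclude_and_rerun()`).
`sd_to_grams()` converts SD-scale results to grams (default 454 g per birth
weight SD, the EGG consortium value).

## The synthetic world

`sim_config()`/`simulate_duos()` generate three generations per SNP —
grandmaternal genotypes in Hardy-Weinberg equilibrium, maternal and
offspring genotypes by Mendelian transmission plus an independent paternal
allele — so mothers' own birth weights (needed for the own-genotype marginal
GWAS) have a coherent generative origin one generation up. Lipids are
genotype scores plus correlated residuals scaled to unit total variance;
birth weight adds the maternal lipid path, the fetal genetic analogue, any
per-SNP direct (pleiotropic) maternal effects, and noise scaled to unit
total variance. Paternal genotype carries no intrauterine path and is
absorbed into residual variation.

`scenario()` provides stated-world presets sharing one skeleton: 185 SNPs
with per-lipid instrument panels of 96/82/60 (50 SNPs on two or more
lipids), allele frequencies uniform on (0.05, 0.95), lipid residual
correlations (HDL-LDL 0.1, HDL-TG -0.4, LDL-TG 0.3, typical of serum lipid
panels), and sample sizes 188,577 / 230,069. Choices the sources leave
open, fixed here once: each lipid's panel explains 10% of its variance
(GWAS-panel scale), with per-SNP variance explained following an
exponential spectrum above a detection floor (association non-centrality
$\ge 9$) because the emulated panel is by construction genome-wide
significant. Presets then vary only the causal/pleiotropic structure:
null, maternal LDL-C effect +0.1, constant +0.02 directional pleiotropy
(signed relative to the exposure-raising allele, so it survives
orientation), InSIDE-violating pleiotropy proportional to instrument
strength, and two breakdown worlds putting ~40% / ~60% of the HDL-C IVW
weight on instruments with a +0.2 Wald-ratio offset.

Two generation routes exist deliberately. The duo-level simulator is the
ground truth for the partition. Replication-heavy calibration (null
coverage, Egger power, breakdown, multivariable recovery) uses
`simulate_summary()`, which draws summary statistics directly from their
asymptotic sampling distributions with SEs matched to the configured sample
sizes (partitioned outcome SEs carry the closed-form $\sqrt{20/9}$
inflation and $-0.8$ maternal-fetal correlation) — individual-level
simulation of 230,069 duos x 185 SNPs x 200 replicates would not fit any
reasonable compute budget.

What the generator does **not** emulate: LD between instruments, assortative
mating, parent-of-origin effects, imputation uncertainty, sample overlap
between sample 1 and sample 2 (overlap within sample 2's two marginal GWAS
*is* modelled via `overlap_fraction`), gestational-age structure, and
selection effects in the source GWAS. A green synthetic test therefore
establishes that the estimators do what their theory promises under the
assumed causal diagram — not that the published numbers are correct.

## Known limitations and honest failures

* The closed-form partition reproduces the *quantity* the published
  structural equation model estimates; numerical equality with published
  SEM output cannot be asserted (different likelihood and overlap
  weighting).
* Published CI widths depend on undocumented fixed-vs-random-effects and
  quantile conventions; only point estimates are reproduction targets.
* One acceptance expectation is knowingly red: "weighted median unbiased
  (within 3 SE) at 40% invalid weight". With 96 instruments and separated
  ratio clusters the weighted median lands near the 83rd weighted
  percentile of the valid ratios; that displacement is ~4 sampling SDs in
  every parameterization we tried, and scales like $\sqrt{L}$, so the
  3-SE bound cannot hold at this panel size. The estimator's breakdown
  *ordering* (worse at 60% than 40%, collapse past 50%) is verified
  instead; the 60% half of the criterion passes as stated.
* The multivariable invariant "an all-zero exposure column leaves other
  estimates unchanged" is unimplementable: a zero column makes the design
  singular, and the fit refuses it by name instead.
* No LD clumping, proxy lookup, Steiger filtering, MR-PRESSO, or power
  calculation; multiple-testing correction is deliberately absent (results
  are reported as per-analysis 95% CIs).
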