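---
title: "Two-sample MR with two-step mediation: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample MR with two-step mediation: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The causal model

Two-sample Mendelian randomization estimates the causal effect of an
exposure X on an outcome Y from two non-overlapping GWAS: per-SNP effects
$\hat\gamma_j$ on X (with SE $\sigma_{\gamma j}$) and $\hat\Gamma_j$ on Y
(with SE $\sigma_{\Gamma j}$). Under the instrumental-variable assumptions
(the SNP associates with X, is independent of confounders, and affects Y
only through X), each SNP's Wald ratio $\hat\Gamma_j / \hat\gamma_j$
estimates the same causal effect, and the estimators differ only in how
they pool the ratios and in which violations they tolerate.

The mediation layer adds a mediator M: the total effect $\beta_c$ of X on
Y decomposes into a direct path $\theta$ and an indirect path
$\beta_a \beta_b$ through M ($\beta_a$: X on M; $\beta_b$: M on Y), so
$\beta_c = \theta + \beta_a\beta_b$. The two-step design estimates
$\beta_c$, $\beta_a$ and $\beta_b$ as three separate pairwise MR analyses
and combines them with the product-of-coefficients method.

## Estimators

**IVW.** Weighted regression of $\hat\Gamma_j$ on $\hat\gamma_j$ through
the origin with weights $1/\sigma_{\Gamma j}^2$. The fixed-effect SE is
$\sqrt{1/\sum \hat\gamma_j^2/\sigma_{\Gamma j}^2}$. When the Cochran Q
statistic over the $k$ ratios is large (p < 0.05 on $\chi^2_{k-1}$), the
multiplicative random-effects (MRE) model inflates the SE by
$\sqrt{\max(1, Q/(k-1))}$; the point estimate is unchanged. The
`max(1, ·)` clamp means apparent underdispersion never shrinks the SE
below the fixed-effect value. Mode `"auto"` implements the
heterogeneity-switch rule and the chosen model is recorded in all outputs.

**MR-Egger.** SNPs are first oriented so $\hat\gamma_j \ge 0$ — the
exposure-increasing-allele frame in which "directional" pleiotropy is
defined — then $\hat\Gamma_j$ is regressed on $\hat\gamma_j$ *with* an
intercept, weights $1/\sigma_{\Gamma j}^2$. The slope is the causal
estimate (consistent under InSIDE); the intercept estimates the average
directional pleiotropic effect. Coefficient SEs are scaled by
$\max(1, \sqrt{RSS/(k-2)})$. P-values use the normal reference by default
(a `p_reference = "t"` flag is available for cross-checking against
implementations that use the t distribution).

**Weighted median.** Wald ratios are sorted and the estimate is the linear
interpolation of the ratio at cumulative normalized weight 1/2, using the
midpoint convention $s_j = \sum_{i\le j} w_i - w_j/2$ with
$w_j = \hat\gamma_j^2/\sigma_{\Gamma j}^2$; it is consistent while valid
instruments carry at least half the weight. The SE is the SD of the
estimate over 1000 parametric-bootstrap resamples in which both
$\hat\gamma_j$ and $\hat\Gamma_j$ are perturbed by their Gaussian SEs;
the bootstrap is seeded and the replicate count is the SE convention, so
two runs with the same seed are identical.

For binary outcomes all betas are log-odds and `to_odds_ratio()`
exponentiates the estimate and its CI bounds. All 95% CIs use the 1.96
normal quantile, matching how such analyses are conventionally reported.

## Instrument selection and harmonization

Selection keeps SNPs with $p \le 5\times10^{-8}$; when fewer than 3
survive, the threshold is relaxed once to $5\times10^{-6}$ (the fallback in
use is recorded); a set still smaller than 3 is flagged unusable and the
analysis is skipped rather than erroring, since in a bidirectional design
the reverse direction routinely lacks instruments. Greedy clumping visits
variants in ascending p-value order (ties broken lexicographically by
variant ID, so the result is independent of row order) and accepts a
variant only if its LD r² with every already-accepted variant within
10,000 kb on the same chromosome is below 0.001. Variants on different
chromosomes never clump. When no LD matrix is supplied the variants are
treated as independent — the post-clumping world the synthetic generator
emulates.

Aggregate instrument strength uses
$F = r^2(N-k-1)/[(1-r^2)k]$ with $r^2 = \sum_j 2p_j(1-p_j)\hat\beta_j^2$
on standardized traits (the standard approximation when per-study variance
explained is not published); per-SNP strength is the single-SNP chi-square
$(\hat\beta_j/\sigma_j)^2$. Sets with $F \ge 10$ are marked retained.

Harmonization aligns outcome records onto the exposure's effect allele:
matching alleles are kept, swapped reports are sign-flipped, strand
complements are resolved, and palindromic variants (A/T, C/G) — whose
labels carry no strand information — are resolved by allele-frequency
sidedness, but dropped whenever either study's EAF falls in
[0.42, 0.58] or is missing. That window is the conventional default for
the "drop ambiguous palindromes" behaviour; it is configurable. Dropped
variants remain in the output table with a flag, so kept + dropped always
equals the shared-variant count.

## Sensitivity analysis

MR-PRESSO computes the observed residual sum of squares
$\sum_j (\hat\Gamma_j - \hat\beta_{(-j)}\hat\gamma_j)^2/\sigma_{\Gamma j}^2$
with leave-one-out IVW fits, and builds its null by redrawing
$\hat\Gamma_j^* \sim N(\hat\beta_{(-j)}\hat\gamma_j, \sigma_{\Gamma j}^2)$
and recomputing the statistic (including the leave-one-out refits) 1000
times by default. Empirical p-values use $(r+1)/(n_{sim}+1)$, so they are
bounded below by $1/(n_{sim}+1)$ and never zero. Per-SNP outlier p-values
are Bonferroni-adjusted within the dataset — more conservative than a raw
per-SNP threshold, chosen deliberately and documented here. A consequence
worth knowing: with $k$ SNPs the smallest achievable adjusted p-value is
$k/(n_{sim}+1)$, so flagging at $\alpha = 0.05$ requires
$n_{sim} > k/0.05$; the function warns when the resolution is
insufficient. The distortion test compares the IVW shift after removing
flagged outliers against shifts from removing random subsets of the same
size.

The clean-up loop follows the rule *remove outliers only when the Egger
intercept indicates pleiotropy*: while intercept p < 0.05, run MR-PRESSO,
drop flagged SNPs, repeat; stop when the intercept is clean, nothing is
flagged, fewer than 4 SNPs remain (warning state), or after 5 rounds. The
Egger intercept test has well-known low power against a *single* outlier:
one aberrant SNP inflates the regression dispersion scale roughly in
proportion to its pull on the intercept, so the intercept z-statistic is
bounded regardless of the outlier's magnitude. The intercept reliably
detects *directional* pleiotropy spread over SNPs — which is exactly the
situation the loop is designed for. Our spike-in experiments therefore
verify two things separately: MR-PRESSO flags a 10×-scale outlier in
essentially every replicate, and, in the replicates where the intercept
does trigger the loop, the loop removes the spiked SNPs and restores
intercept p ≥ 0.05.

## Mediation

The indirect effect is $\beta_a\beta_b$ with the first-order delta-method
SE $\sqrt{\beta_a^2\sigma_b^2 + \beta_b^2\sigma_a^2}$ — deliberately
first-order rather than second-order (which adds
$\sigma_a^2\sigma_b^2$), so that the CI and the Sobel z-test
$z = \beta_a\beta_b / SE$ share one denominator and can never disagree; a
`second_order` flag provides the larger SE when wanted. The proportion
mediated is $\beta_a\beta_b/\beta_c$, reported in percent, with a
delta-method CI for a ratio that assumes the numerator and denominator are
independent — justified by the three analyses using non-overlapping GWAS
samples, and documented as an assumption. When the total effect is not
significant at 0.05 the proportion is suppressed (NA) while the indirect
effect is still reported: an exposure can act on the outcome entirely
through the mediator (the spine-OA pattern), and a proportion of a
non-significant total is not interpretable.

## FDR correction

Published q-values in this literature are sometimes inconsistent with any
single BH family (q < p cannot arise from BH). The package therefore fixes
the family explicitly: q-values are computed per estimator method across
the analyses of one pipeline run, via the standard step-up procedure, and
the family definition travels with the output.

## The synthetic generator

`sim_config()` defaults are the study conditions the package is validated
under, chosen to mirror a large-biobank two-sample setting: 300
instruments jointly explaining 10% of exposure variance (the scale of a
~400-instrument panel for a well-powered protein GWAS), exposure/outcome/
mediator sample sizes of 435,516 / 400,000 / 681,275, MAF uniform on
[0.05, 0.5], and knee-OA-scale effects ($\theta = 0.042$,
$\beta_a = 0.04$, $\beta_b = 0.663$, total 0.0685). True instrument
effects are Gaussian, rescaled so $\sum_j 2p_j(1-p_j)\gamma_j^2$ equals
the target $r^2$; observed effects add noise with
$\sigma = 1/\sqrt{2p(1-p)n}$, the SE of a per-allele regression
coefficient on a standardized trait. Binary outcomes are approximated by
the same Gaussian machinery on the log-odds scale — summary-level MR
consumes only (beta, SE), so exact liability-scale modelling would change
nothing downstream.

Pleiotropic effects (mean, SD, and the fixed effects given to outlier
SNPs) are applied in the exposure-increasing-allele frame
(multiplied by $\mathrm{sign}(\gamma_j)$), so that a nonzero
`pleiotropy_mean` is directional in precisely the sense the Egger
intercept tests; without this orientation a constant "directional" effect
would be sign-balanced after Egger's orientation step and undetectable by
construction. The mediation triplet generator gives the mediator its own
disjoint SNP panel: if the M→Y analysis reused the X instruments, its Wald
ratios would estimate $(\theta + \beta_a\beta_b)/\beta_a$ — a mixture of
paths — rather than $\beta_b$. Each pairwise dataset receives fresh
observation noise, emulating three independent samples. One global seed
governs all draws; identical configurations with identical seeds are
bit-identical.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: LD between instruments (instruments are
born independent; clumping is exercised through explicitly supplied LD
matrices), sample overlap between the two GWAS, winner's-curse bias from
selecting instruments in the same sample they are estimated in,
liability-scale subtleties of binary traits, population stratification,
and missingness/proxy-SNP issues.

## Numerical choices and degenerate inputs

* P-values are floored at the smallest positive double so extreme
  associations never underflow to an invalid 0.
* A single-SNP dataset degenerates IVW to the Wald ratio; Egger and the
  weighted median require 3 SNPs, MR-PRESSO 4; below these the functions
  error with the required count.
* Weighted-median interpolation clamps to the extreme ratios when half
  weight falls outside the midpoint grid (a single dominant SNP returns
  its own ratio).
* Cochran Q with identical ratios returns Q = 0, p = 1.
* Clumping tie-breaks (equal p-values) use lexicographic variant order for
  determinism.

## Problem sizes used in validation

The test suite validates calibration with 200 replicates of 300-SNP
pleiotropy-free panels (Egger intercept type-I rate and IVW coverage),
spike-in detection with 100 replicates of 50-SNP panels with one
10×-scale outlier, estimator equivalence against independent
least-squares and weighted-quantile oracles on 100 random 50-SNP
datasets, and mediation recovery over 200 simulated triplets plus 500
null replicates for the Sobel test. These sizes give Monte-Carlo SEs a
few times smaller than the tolerances asserted.

## Known limitations

Proxy-SNP lookup, LD computation from reference genotypes, multivariable
MR, and multiple mediators are out of scope. The Egger intercept's low
power against isolated outliers (discussed above) is a property of the
method, not of this implementation; users worried about single invalid
instruments should read the MR-PRESSO outlier flags and the leave-one-out
table directly rather than relying on the intercept-triggered loop alone.
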