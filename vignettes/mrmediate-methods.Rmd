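---
title: "Methods: two-sample MR mediation on summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR mediation on summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The design

`mrmediate` implements a two-step summary-statistics MR design. Step one
screens many candidate exposures (bacterial taxa) and candidate mediators
(plasma metabolites) against a binary outcome with forward MR in each
outcome cohort, pools surviving cohorts by fixed-effects meta-analysis, and
checks the reverse direction for identified exposures. Step two estimates,
for each identified taxon–metabolite pair, how much of the taxon's total
effect on the outcome flows through the metabolite.

MR treats genetic variants as instrumental variables. The causal
interpretation rests on the three IV assumptions: the variant is robustly
associated with the exposure (relevance), independent of confounders of the
exposure–outcome relation (exchangeability), and affects the outcome only
through the exposure (exclusion restriction). The estimators and
diagnostics in the package are all aimed at enforcing or probing these
assumptions from summary data alone.

## Instrument selection and harmonisation

Candidate instruments pass, in order:

1. **Association threshold** `iv_pvalue_threshold = 5e-6` (strict
   inequality). The conventional genome-wide 5e-8 is carried in the
   configuration for accounting; the looser working threshold is the
   standard compromise for low-heritability microbiome and metabolite
   GWAS, which would otherwise yield too few instruments.
2. **Greedy LD clumping**, window 10,000 kb, `r2 < 0.001`: variants are
   ranked by p-value (ties broken lexicographically by variant id so the
   result is order-independent), the best variant is accepted and every
   remaining variant within the window with squared correlation at or above
   the bound is removed, repeatedly. The output is verified in tests
   against an exhaustive pairwise oracle.
3. **Weak-instrument filter**: F = beta^2/se^2 must be at least 10; the
   exclusion is of instruments *strictly below* 10, so F = 10 is retained.
4. **Outcome-association exclusion**: instruments with an outcome p-value
   below 5e-6 are removed as likely exclusion-restriction violations.
   Instruments absent from the outcome file are untouched by this filter
   (they are later dropped as missing during harmonisation; proxy variants
   are never substituted).

Harmonisation aligns the outcome effect onto the exposure's effect allele:
matching allele pairs pass through, swapped pairs have the outcome beta
negated and frequency complemented, anything else is dropped as a mismatch.
Strand-flip rescue is deliberately not attempted — with unknown strand
conventions a complement match is indistinguishable from a genuinely
different variant, and dropping is the conservative reading. Palindromic
variants (A/T, G/C) cannot be strand-resolved from alleles alone; they are
dropped when the exposure effect-allele frequency lies within
`palindrome_maf_halfwidth = 0.08` of 0.5 (window \[0.42, 0.58\], boundary
inclusive with a 1e-9 numeric tolerance) or when the frequency is missing.
Non-ambiguous palindromic variants are retained as-is, without
frequency-based re-orientation. Every input instrument ends up either
retained or counted exactly once in the drop log; this accounting identity
is asserted in the test suite.

## The estimator suite

With harmonised pairs (b_x, se_x, b_y, se_y), the per-variant Wald ratio is
b_y/b_x with first-order standard error se_y/|b_x|; the uncertainty in b_x
is ignored, the conventional default (a second-order correction changes
estimates by O(1/F) and is out of scope).

- **IVW**: the precision-weighted mean of ratios, identical to no-intercept
  WLS of b_y on b_x with weights 1/se_y^2 (asserted to 1e-10 against both
  oracles). The multiplicative random-effects standard error inflates the
  fixed-effects one by max(1, sqrt(Q/(J-1))) — floored at 1 so random
  effects never claim more precision than fixed effects. Normal inference,
  95% CI at ±1.959964·se.
- **Cochran's Q** with chi-square(J−1) upper tail measures ratio
  heterogeneity.
- **MR-Egger** first orients every variant so b_x ≥ 0 (the intercept is
  only interpretable as average directional pleiotropy in that
  orientation), then fits weighted least squares *with* an intercept;
  inference for slope and intercept uses t(J−2), i.e. the residual scale
  is estimated, which keeps the intercept test calibrated under balanced
  pleiotropy that the weights do not model.
- **Weighted median**: ratios are sorted, the cumulative weight midpoint
  s_j = Σ_{k≤j} p_k − p_j/2 is interpolated at 0.5; the standard error
  comes from a parametric bootstrap (each ratio re-drawn from its normal;
  default 1000 draws, seeded).
- **MR-PRESSO**: the observed statistic is the sum of squared residuals
  from leave-one-out IVW slopes; its null distribution is simulated by
  re-drawing each b_y from N(b_x·beta^(−j), se_y^2) and recomputing the
  statistic in full (including the leave-one-out slopes). P-values use the
  add-one estimator (1 + #{sim ≥ obs})/(n_sim + 1), so they are never
  zero. Per-variant outlier p-values are Bonferroni-corrected across the J
  variants; when outliers are found, the corrected estimate is the IVW on
  the remainder. Four variants are the hard minimum. Note the outlier
  test's floor p of 1/(n_sim+1) must be below alpha/J to flag anything:
  the default `n_sim = 1000` supports up to J = 50 at alpha = 0.05.

The distortion test of the reference MR-PRESSO formulation is omitted: the
screening rules use only the global test and the outlier list.

## Screening and meta-analysis

Each per-cohort analysis is excluded when (checked in this fixed order,
first hit wins): fewer than `min_snps = 4` variants; Egger intercept
p < 0.05; PRESSO global p < 0.05; Cochran's Q p < 0.05; or sign discordance
between the IVW point estimate and the weighted median or Egger slope.
"Inconsistency with the sensitivity analyses" has no standard quantitative
definition; sign discordance of point estimates is the weakest defensible
reading and is the one implemented. Exclusion is per cohort: surviving
cohorts are pooled by fixed-effects inverse-variance meta-analysis, whose
heterogeneity statistic is reported but does not itself exclude.

Pooled p-values are classified against `alpha/n_tests` (Bonferroni;
denominators are configuration values, being properties of the input
inventory — 416 taxa and 1178 metabolites by default) and a suggestive band
up to `alpha = 0.05`.

## Simplified LD-score regression

For each trait the chi-square statistics z² are regressed on LD scores
(weights 1/max(l, 1)); heritability is slope·m/N̄. Cross-trait, the
products z₁·z₂ are regressed on LD scores; the slope scaled by
m/sqrt(N̄₁N̄₂) is the genetic covariance and rg follows by normalising with
the univariate heritabilities. Standard errors come from a delete-one-block
jackknife over `n_blocks = 20` contiguous blocks (reference implementations
use ~200 blocks over genome-wide panels; 20 suits desk-scale panels of a
few thousand variants). Deviations from reference implementations, accepted
for simplicity: single-step weighting instead of iterated
heteroscedasticity weights, and no sample-overlap intercept modelling.
Estimates of rg are clipped to \[−1.25, 1.25\] with a warning outside
\[−1, 1\]; a nonpositive heritability estimate makes rg undefined and is
raised as an error the pipeline catches and reports rather than fails on.
The shared-variant set is taken in panel order, making the estimate exactly
symmetric in the two traits.

## Mediation

The indirect effect is the product of coefficients ME = β_EM·β_MO, where
β_EM is the taxon→metabolite IVW estimate and β_MO the univariable
metabolite→outcome estimate (no multivariable adjustment is attempted — a
known limitation: if the taxon affects the outcome through paths correlated
with the metabolite's instruments, β_MO absorbs them). The total effect is
the taxon's pooled meta-analysis log-OR, the direct effect is total − ME
(exact by construction), and the mediated proportion ME/total is reported
as a signed fraction — values outside \[0, 1\] indicate inconsistent
mediation and are flagged, never clipped.

The CI is a percentile bootstrap: `n_boot = 1000` independent draws of the
two coefficients from their normal distributions, product formed, 2.5/97.5
linear-interpolation percentiles; the p-value is the two-sided sign
probability floored at 2/(n_boot + 1). The two coefficient draws are
independent, which is exact here because the two legs come from different
GWAS cohorts. A delta-method (Sobel) standard error is reported alongside
for comparison. Bootstrap output is a pure function of the seed.

Pairs enter mediation when their taxon→metabolite IVW p-value passes
Bonferroni over the attempted pairs (all identified taxa × all identified
metabolites are attempted; the attempted count is always the full product).

## The synthetic-data generator

`simulate_study()` emulates a five-source summary-statistics study: one
microbiome cohort (default N = 5,959, SD units), one metabolite cohort
(N = 8,299, SD units), and three case-control outcome cohorts
(4,801/405,229, 234/413,908 and 3,972/52,665 — jointly 9,007 cases and
871,802 controls, prevalence ≈ 1.02%) on the log-odds scale.

Generation is analytic: estimated betas are truth-implied marginal effects
plus multivariate normal noise whose correlation equals the LD panel
(block-diagonal AR(1)) and whose per-variant scale is the analytic standard
error 1/sqrt(2p(1−p)N), with the effective sample size
4/(1/n_case + 1/n_control) for the binary outcome. No individual-level
genotypes are simulated — orders of magnitude faster and sufficient to
exercise every downstream stage. The causal chain is explicit: exposure
instruments (effects gamma, variance explained `h2_exposure = 0.08` over 30
instruments by default, echoing the modest instrument strength of
microbiome GWAS), mediator-specific instruments (delta, `h2_mediator =
0.1` — the mediator's own genetics, required for the mediator→outcome leg
to be identifiable), effects theta_em, theta_mo, theta_dir, and optional
direct variant→outcome pleiotropy alpha on the exposure instruments.

Two generator choices deserve note:

- Instrument magnitudes are uniform in a 0.8–1.2 band (signed, then scaled
  to the target variance explained) rather than normal. Normal draws put a
  sizeable mass near zero, so "n instruments" would really mean "n minus
  the near-null ones", and the near-threshold survivors carry winner's
  curse into every recovery analysis. The bounded band makes the
  configured instrument count the effective one.
- Directional pleiotropy (`pleiotropy_mean ≠ 0`) is applied relative to
  the exposure-increasing allele. Since allele labels are arbitrary, a
  mean defined without that orientation would cancel under MR-Egger's
  b_x ≥ 0 orientation and be undetectable by construction.

What the generator does **not** emulate: microbiome compositionality,
imputation quality, sample overlap between cohorts, non-normal effect-size
distributions, population stratification, or real LD beyond block-AR(1).
Passing tests therefore demonstrate the correctness and calibration of the
estimators under their own model, not robustness to those real-data
complications.

Instruments are placed one per LD block before doubling up, so clumping
removes LD-tagged neighbours but not distinct instruments. Block positions
are spaced 20,000 kb apart (variants within a block 1 kb apart), so the
10,000-kb clumping window cleanly separates blocks.

## Validation suites and problem sizes

The test suite works at sizes chosen to keep a full run around a minute
while leaving the statistical checks sharp:

- Null calibration: 500 replicates of a 30-instrument study at effective
  N = 50,000 on both sides; the random-effects IVW, Egger intercept,
  Cochran Q and PRESSO global (n_sim = 200) rejection rates are required
  to fall in the 99% binomial band around 0.05.
- Recovery: 200 replicates with theta_em = 0.1, theta_mo = 0.6,
  theta_dir = 0.14 (total 0.2, mediated proportion 0.3) at N = 50,000 per
  leg; means are required within 3 Monte-Carlo standard errors of truth.
  The mediator→outcome leg in this design keeps instrument leakage
  negligible (exposure instruments reach the mediator only attenuated by
  theta_em) and its instruments clear of the outcome-association filter.
- LDSC: rg = 0.5, h² = 0.3/0.3, m = 2,000 variants in AR(1) blocks,
  N = 20,000, 20 jackknife blocks, 100 seeds; 95% of estimates must lie
  within 3 jackknife SE of truth.
- Robustness: a +10·se single outlier among 6 instruments must be flagged
  and repaired (with J ≳ 12 the "repair improves the estimate" property is
  not attainable for a single 10·se outlier, since the raw bias shrinks as
  1/J while the corrected estimate's noise shrinks only as 1/sqrt(J));
  with 40% directionally invalid instruments among 30 the weighted median
  must beat IVW in at least 90% of replicates.
- Determinism: a complete `run_study()` is rerun with the same
  configuration and compared file-by-file for byte identity; the report
  writer emits no timestamps and full-precision numbers for this reason.

At the default study-scale sample sizes the package's estimates display
honest finite-sample behaviour — notably winner's-curse attenuation of the
exposure legs at N = 5,959 — which is why the recovery suites state their
own (larger) sample sizes rather than the defaults.

## Known limitations

- First-order Wald ratio standard errors; no Steiger filtering,
  multivariable MR, MR-RAPS or mode-based estimators.
- The mediator→outcome coefficient is univariable (see above).
- LDSC-lite is a teaching-grade implementation: adequate for synthetic
  recovery, not for parity with genome-wide reference software.
- The outcome-association exclusion filter, taken from the screening
  design, can remove genuinely causal instruments when the mediator or
  exposure effect is strong relative to the outcome GWAS noise; it is a
  screening device, not a bias correction.
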