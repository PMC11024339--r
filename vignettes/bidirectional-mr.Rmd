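---
title: "Bi-directional two-sample Mendelian randomization with bidirMR"
author: "bidirMR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bi-directional two-sample Mendelian randomization with bidirMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bidirMR)
```

## The design

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure on an outcome using genetic variants as instrumental variables,
with the exposure and outcome associations taken from different GWAS
cohorts so that only per-SNP summary statistics are needed. A variant is a
valid instrument when it is (i) robustly associated with the exposure,
(ii) independent of confounders of the exposure-outcome relationship, and
(iii) affects the outcome only through the exposure. bidirMR implements
the full design for a grid of exposures and outcomes run in both
directions — here, autoimmune diseases (binary, log-odds effects) against
sarcopenia-related traits such as hand-grip strength, fat-free mass and
walking pace (continuous) — with each direction gated by its own
Bonferroni threshold, alpha divided by that direction's number of exposure
factors: 0.05/6 (printed 0.008) with six disease exposures forward,
0.05/8 (printed 0.006) with eight trait exposures in reverse. Gating uses
the exact quotient; reports carry both the exact and the printed value.

## Instrument selection

Selection enforces the three instrument assumptions in sequence, and the
per-stage attrition is logged on the returned `InstrumentSet`:

1. **Relevance.** Keep variants with exposure association `p < 5e-8` and
   instrument strength `F = (beta/se)^2 > 10`, both strict. At `p < 5e-8`
   the implied F already exceeds 29, so the F rule only bites when the
   caller relaxes the p threshold.
2. **Independence of LD.** Greedy clumping at `r^2 < 0.001` within a
   1000 kb window: variants are visited in order of ascending p-value
   (ties broken by chromosome, then position, for determinism) and every
   not-yet-assigned variant on the same chromosome within the window at
   `r^2 >=` threshold is discarded. The window is read as +/- 1 Mb around
   the index variant, the usual clumping-tool geometry. r-squared comes
   from an `LdReference`: either squared Pearson correlation of an
   allele-dosage panel or a precomputed pair map. A pair absent from a
   precomputed map inside the window is kept with a warning — unknown LD
   is not treated as grounds to discard an instrument.
3. **Independence of confounders.** Variants annotated (case-insensitive)
   to smoking, body mass index, physical inactivity, malnutrition or
   extreme sleep duration at `p < 5e-8` are removed, emulating a
   PhenoScanner screen from a local annotation table. The screening
   p-value is this package's choice; the annotation source never states
   one.

Records without an effect-allele frequency are ineligible as instruments,
because the downstream minor-allele-frequency rule could not be certified
for them.

## Harmonization

The exposure's allele coding is the reference frame; only the outcome
record is modified. For each instrument found in the outcome table:
palindromic exposure variants (A/T or C/G) are dropped unconditionally —
no frequency-based strand inference is attempted; outcome alleles matching
in order are kept as-is; matching in swapped order negates the outcome
beta and reflects its frequency; otherwise the outcome alleles are
strand-complemented and rechecked; residual mismatches drop as
incompatible. After alignment, a record is dropped unless the minor-allele
frequency strictly exceeds 0.01 on *both* sides (the conservative reading:
the filter's side is not stated by convention), or when a frequency is
missing. Every instrument lands exactly once in the aligned pairs or the
drop log, which the class validity enforces.

## Estimators

All five estimators consume per-SNP Wald ratios
`ratio_j = beta_out_j / beta_exp_j` with first-order standard errors
`se_out_j / |beta_exp_j|`, i.e. inverse-variance weights
`w_j = beta_exp_j^2 / se_out_j^2` that ignore exposure-side noise (the
NOME approximation). This makes the ratio-meta-analysis and
origin-regression forms of IVW identical, which the test suite checks
against an independent weighted-least-squares oracle at 1e-10.

* **IVW** — weighted mean of ratios; Cochran's
  `Q = sum w_j (ratio_j - beta)^2` on `k - 1` df measures heterogeneity.
  When the Q p-value is below 0.05 the multiplicative random-effects
  standard error (fixed SE times `max(1, sqrt(Q/(k-1)))`) is used,
  otherwise the fixed-effect `sqrt(1/sum w_j)`; the switch is recorded
  per pair. Inference is two-sided normal, 95% CI at z = 1.959964.
* **MR-Egger** — weighted regression with free intercept after orienting
  every variant to `beta_exp >= 0`; the intercept estimates directional
  pleiotropy, the slope the causal effect. Standard errors carry the
  residual scale floored at 1 and p-values use t on `k - 2` df.
* **Weighted median** — ratios sorted, estimate interpolated where the
  cumulative weight midpoint crosses one half; consistent while valid
  instruments hold at least half the weight. The standard error is a
  parametric bootstrap (default 1000 draws, explicit seed): effects
  resampled from normals at their reported SEs, the median recomputed,
  SE taken as the standard deviation across draws.
* **Penalized weighted median** — each variant's heterogeneity
  `q_j = w_j (ratio_j - theta_hat)^2` is converted to an upper chi-square(1)
  tail probability and the weight multiplied by `min(1, 20 p_j)`; the
  weighted median is recomputed under the penalized weights, and the
  bootstrap repeats the whole procedure per draw. Penalty constant 20 is
  the conventional choice; a penalty of 0 removes all weight and is
  reported as a degenerate-weights error.
* **Profile maximum likelihood** — minimizes
  `L(theta) = sum_j (beta_out_j - theta beta_exp_j)^2 /
  (se_out_j^2 + theta^2 se_exp_j^2)`, the profile objective of the
  bivariate-normal measurement model, so exposure-side noise is modelled
  here. Optimized on a bracket of half-width `10 * max(|IVW|, 0.1)` (the
  floor keeps the bracket non-degenerate when the IVW estimate is near
  zero) at tolerance 1e-10; an optimum pinned to the bracket edge is
  reported as an estimation failure. The SE comes from the curvature of
  `L/2` at the optimum by central differences; in the limit of vanishing
  exposure noise the estimate and SE collapse to fixed-effect IVW.

Minimum instrument counts: 2 for IVW and maximum likelihood, 3 for
MR-Egger and both medians; a pair failing a minimum records the method as
not estimable rather than failing the run. For binary outcomes every
estimate and CI is exponentiated to an odds ratio; the p-value and
log-scale SE are unchanged.

## MR-PRESSO

The global test computes, per variant, the leave-one-out IVW slope and the
weighted squared residual of the held-out variant; the observed residual
sum is compared against `n_sim` Monte-Carlo replicates drawn from the
no-pleiotropy model (exposure effects resampled at their SEs, outcome
effects at the leave-one-out expectation). Both the global and the
per-variant p-values use the +1-corrected exceedance fraction, so the
global p can never fall below `1/(n_sim+1)`; per-variant p-values are
Bonferroni-multiplied by k and flagged below 0.05. Removal iterates —
re-test, re-remove — until nothing is flagged, fewer than four variants
remain (the minimum that leaves three-variant leave-one-out slopes), or
ten rounds have run. A consequence of the +1 correction worth knowing: at
`n_sim = 200` and k = 20 the smallest attainable adjusted p is
20/201 ≈ 0.1, so outlier *detection* needs the default `n_sim = 1000`;
200 simulations remain adequate for the global heterogeneity p. The
distortion test is deliberately omitted (detection and removal only), and
the run manifest says so.

## The synthetic-data generator

`simulatePair()` generates exposure/outcome table pairs directly on the
summary-statistic scale: true instrument effects
`gamma_j ~ N(0, gammaSd = 0.1)`, per-SNP standard errors uniform on
(0.005, 0.015) exposure-side and (0.01, 0.02) outcome-side, outcome means
`theta * gamma_j + alpha_j`. The `(gamma, observed beta)` pair is redrawn
until the observed exposure association passes 5e-8, so labelled
instruments survive selection by construction; the small winner's-curse
attenuation this leaves in ratio estimates (about 1% at the default noise
levels, since weights ignore exposure noise) is visible in the recovery
runs below and accepted — modelling selection bias is out of scope.
Pleiotropy models: balanced (`alpha ~ N(0, sd)`), directional
(`alpha = sign(gamma) * N(mean, sd)` — aligned with the
exposure-increasing allele, the allele-coding-invariant sense in which
directional pleiotropy biases IVW; an orientation-free draw would cancel
on the ratio scale because gamma is symmetric about zero), and designated
outliers with a stated direct effect. Alleles include a configurable
palindromic fraction; outcome records are strand-complemented with
probability 0.05 and allele-swapped with probability 0.5, which
harmonization must undo. P-values are floored at the smallest positive
double. `simulateLdPanel()` builds a 500-sample dosage panel from shared
latent block variables (loading `sqrt(r)`, dosages clipped to [0, 2]);
`simulateStudy()` assembles the full 6 x 8 world on a shared ~200-variant
universe — each trait owns 12 instruments, the first two in a 2-variant
LD block that clumping must merge, 10 variants act through screened
confounders, and all true causal effects run forward (reverse analyses
probe the null at -0.25/0 effects).

What the generator does *not* emulate: individual-level genotypes,
population structure, sample overlap between cohorts, winner's curse, or
correlated pleiotropy (violations of InSIDE beyond the directional-mean
model). Passing calibration on this generator therefore certifies the
pipeline's arithmetic and its behaviour under the stated violation models,
not robustness to every failure mode of real GWAS data.

## Problem sizes and numerical choices

The packaged checks run at: 200 random instances for the
estimator-vs-WLS oracles (agreement to 1e-10); 1000 replicates of 30
instruments for null calibration (type-I error inside the exact binomial
95% band around 0.05, Cochran's Q against chi-square(29) by
Kolmogorov-Smirnov at 0.01); 1000 replicates of 50 instruments for
recovery at theta = 0.3 (mean within 0.01, coverage in [0.93, 0.97]); 500
replicates for the weighted-median robustness comparison at 40% invalid
instruments; 100 seeded replicates for MR-PRESSO detection; and the full
6 x 8 bi-directional grid (96 pair analyses, MR-PRESSO at 200
simulations, 1000-draw bootstraps), which completes in well under a
minute single-threaded and is bit-identical when rerun under the same
master seed — every stochastic step draws its seed deterministically from
it. Ties in the clump ordering break by (chromosome, position); degenerate
inputs (zero exposure effects, all-zero penalized weights, optimizer at
the bracket edge, fewer instruments than a method's minimum) are classed
error signals that the pipeline converts to per-pair statuses instead of
aborting the grid.

## Limitations

Real-data ingestion is limited to delimited summary-statistic tables with
a column map; GWAS-VCF/BGEN and live PhenoScanner or LD-server queries are
out of scope, as are MR-RAPS, mode-based estimators, Steiger filtering,
multivariable MR, and the MR-PRESSO distortion test. Odds ratios are
`exp(beta)` of the log-odds causal estimate; no rescaling to per-SD units
is attempted.
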