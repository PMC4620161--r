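---
title: "Testing hemodynamic-response shape at the group level"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing hemodynamic-response shape at the group level}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdrshape)
```

## The problem

When the hemodynamic response (HDR) to a stimulus is estimated at the
subject level with a single canonical waveform, each subject contributes one
number per condition and group analysis is a t-test or ANOVA. Estimating
the response *shape* instead — with m basis functions such as TENT/FIR
kernels, so each subject contributes m effect estimates sampled along the
response — preserves information about rise speed, peak latency, undershoot
and recovery, but poses the group-level question: how should m simultaneous
estimates per subject be tested?

`hdrshape` implements the main answers within one multivariate framework.

## The multivariate model

Across n subjects, stack the per-subject estimates into the n × m matrix B
and model

$$ B_{n\times m} = X_{n\times q}\,A_{q\times m} + D_{n\times m}, $$

where X holds only between-subject variables (intercept, grouping factors,
covariates, their interactions), A is the coefficient matrix, and the rows
of D are i.i.d. m-variate Gaussian with unstructured covariance Σ. Each of
B's columns shares the same X, so `fit_mvm()` is column-wise least squares;
the multivariate structure enters only through the residual
sum-of-squares-and-products matrix E = (B − XÂ)ᵀ(B − XÂ) with n − q error
degrees of freedom. All tests are general linear hypotheses L A M = 0: the
rows of L pick the between-subject effect, the columns of M the component
combination.

Factor coding defaults to effect (deviation) coding so the intercept is the
across-group average, and covariates may be centered globally or within
group; within-group centering makes a group effect interpretable as the
group difference at each group's own covariate mean. Treatment coding and
uncentered covariates remain available. Unbalanced groups are supported
throughout; balance is never assumed outside test fixtures.

## The test families

For a single tested contrast row (one- and two-sample prototypes, g = 1):

* **MVT** (`mvt_general`): the m estimates are simultaneous response
  variables; H₀ is the origin of ℝᵐ (or equality of two group centroids).
  Hotelling T², exact F with df (m, n − m − q + 1). The most faithful
  hypothesis, but the denominator DF shrinks with m, so power suffers at
  small n.
* **XUV** (`xuv_interaction`): the effect-by-component interaction tested
  as a univariate repeated-measures F on contrast-transformed data, df
  (m − 1, (m − 1)(n − q)). It asks whether profiles are parallel, so a
  flat-but-nonzero profile (or two parallel profiles) is invisible to it.
  Pooling contrasts assumes sphericity; a Greenhouse–Geisser estimate of ε
  (Huynh–Feldt optional) multiplies both DFs by default.
* **XMV** (`xmv_interaction`): the same parallelism hypothesis with the
  m − 1 contrast variables treated multivariately; exact T² for g = 1, df
  (m − 1, n − m − q + 2). Requires n − q ≥ m − 1 and therefore refuses
  rank-deficient reconstructed estimates.
* **AUC** (`reduce_components` + `reduced_test`): per-subject sum of the m
  estimates (area under the curve), then a univariate F, df (1, n − q).
  Sensitive to overall amplitude only: curves that differ in shape but not
  area are invisible.
* **L2D**: per-subject Euclidean norm of the m estimates, same univariate
  F. For estimated-shape inputs the norm is unsigned and therefore
  non-Gaussian under the null; the one-sample test is implemented exactly
  as practiced (a t-test on the norms) and its inflated false-positive rate
  is reproduced, deliberately, in the simulation study. For
  canonical-plus-derivative (adjusted-shape) inputs the norm may be signed
  by the canonical coefficient (`signed = TRUE`).
* **LME** (`fit_lme_shape` + `lme_omnibus`): for one group with no other
  explanatory variables, the cell-mean-coded mixed model
  β\_ij = α\_j + δ\_i + ε\_ij with a random per-subject shift δ\_i, and the
  Wald F of H₀: α₁ = … = α\_m = 0. The cell-mean coding cannot coexist
  with other between-subject variables (the design would be
  over-parameterized), so such input is refused rather than reinterpreted.

Hypotheses with several contrast rows (multi-level factors) use Pillai's
trace by default — the most robust of the classical MANOVA statistics —
with Wilks' lambda selectable; for g = 1 all classical statistics coincide
with T², which is computed exactly.

Because the families carry different DFs, results are also reported as
standard-normal equivalents `z = qnorm(1 − p)` computed on the log scale
(`f_to_z`), finite down to double-precision underflow.

### Numerical choices

* Orthonormal polynomial contrasts are the default M for interaction
  tests; any zero-sum basis of the same span gives identical results
  (M is re-orthonormalized internally), which the suite verifies.
* The Greenhouse–Geisser ε is the Box estimate from the contrast-error
  covariance, clamped to [1/(m−1), 1]; Huynh–Feldt applies the usual
  (n − q + 1)-based correction, capped at 1. ε scales both DFs and never
  changes the F value itself.
* An exactly null tested effect (e.g., all-zero data, or identical
  columns under a contrast) returns F = 0 and p = 1 without attempting to
  invert a degenerate error matrix; a singular error matrix with a
  non-null effect is an error, not a silent repair.
* Two-sample tests on reduced values use the pooled-variance form,
  consistent with the homoscedastic multivariate model; a Welch variant
  can be obtained by running `t.test` on the output of
  `reduce_components` directly.
* The LME denominator DF uses the Satterthwaite approximation by default,
  with the balanced-model residual DF (nm − m − 1) as a selectable
  fallback; in this balanced one-group design the two nearly coincide at
  typical n, and the choice is recorded in the returned object.

## The simulation study

`make_scenario` + `simulate_betas` draw per-subject component estimates
directly at the group level: each subject's length-m row is multivariate
Gaussian around a mean HDR curve with covariance σ²ρ^|i−j| (AR(1)), the
minimal structure that keeps simulated curves smooth. The six named
scenarios use m = 7 components at TR = 2 s and ρ = 0.3:

| scenario | groups | effect | σ |
|---|---|---|---|
| 1a | 1 | small undershoot | 1.8 |
| 1b | 1 | moderate undershoot | 1.8 |
| 2a | 2, homoscedastic | 2× amplitude difference | 0.5 |
| 2b | 2, homoscedastic | 2 s peak-latency shift, equal amplitude | 0.3 |
| 3a | 2, heteroscedastic | 2× amplitude difference | 0.3 (group 1) |
| 3b | 2, heteroscedastic | 2 s peak-latency shift | 0.3 (group 1) |

Design choices where the scenario description leaves freedom, fixed once:

* **Waveform.** Mean curves are a parametric difference of gamma bumps: a
  response peaking at 5 s minus a scaled, delayed undershoot, normalized
  to peak amplitude 1 (percent-signal-change scale). Undershoot depth is
  0.10 ("small") and 0.30 ("moderate"). The latency-shift scenarios delay
  the whole waveform by one TR, so the second group's samples are an exact
  grid-shifted copy with identical peak amplitude.
* **Sampling grid.** Samples are taken at t = TR, 2·TR, …, m·TR rather
  than from t = 0: a TENT estimate at stimulus onset is essentially zero
  and carries no shape information. The origin is configurable.
* **Heteroscedasticity.** The group-2/group-1 σ ratio in 3a/3b is 2
  (configurable); group 1 keeps the nominal σ. The two-group analyses
  always use the homoscedastic machinery — the variance mismatch is the
  point of these scenarios, probing robustness.
* **Seeding.** One master seed; each replicate derives its own seed from a
  counter, so studies are reproducible and cells independent.

`run_study` sweeps scenario × regime × n: the FPR regime nulls the tested
effect (zero mean for one group, a shared mean curve for two) while keeping
the covariance structure; the power regime uses the scenario means.
Rejections are counted at α = 0.05; replicates that fail to fit at tiny n
are counted as non-rejections and tallied, never dropped. The defaults run
1000 replicates per cell — rejection-rate orderings and calibration checks
stabilize well below that — with larger counts a parameter away. The
package's own acceptance checks use 2000–2500 replicates for calibration,
1000 for the power orderings at n = 30, and 400 per point for the
sample-size sweep over n = 9, …, 30.

What the simulation does *not* emulate: first-level estimation noise and
its reliability differences across subjects (betas are drawn directly at
the group level), temporal autocorrelation of raw BOLD noise, spatial
structure, and multiple-testing across voxels. Passing tests therefore
speak to the group-level operating characteristics of the tests under a
Gaussian AR(1) world, not to end-to-end pipelines on real data.

## What the study reproduces

* MVT, XUV (GG), XMV, AUC, and LME hold the false-positive rate at the
  nominal 0.05 (XUV with GG runs slightly conservative, as the correction
  is known to do).
* Unsigned one-group L2D inflates the false-positive rate drastically —
  the norms are positive by construction, so the one-sample t-test is
  answering a different question. This pathology is reproduced on purpose.
* With one group, LME is the most powerful valid test; XUV consistently
  beats XMV; AUC is essentially blind to the equal-area latency-shift
  scenario that XUV detects with high power; and power is non-decreasing
  in n for every valid method.

## Voxelwise application

`run_voxelwise` applies the same machinery per voxel of NIfTI images (one
volume per component per subject, described by a manifest), writing F and Z
maps plus a computable-voxel mask; non-computable voxels carry a sentinel 0
rather than NaN. Table mode and voxelwise mode share one code path, and the
suite checks they agree voxel-for-voxel. The tool never resamples or
reorients: a grid mismatch is an error.

## Limitations

* The multivariate model assumes a common Σ across between-subject cells;
  heteroscedastic data are handled only in the sense of the robustness
  scenarios, not modeled.
* No permutation or bootstrap inference, and no multiple-testing
  correction — downstream cluster-level or FDR control is a separate
  concern.
* First-level reliability is not propagated; subjects are weighted
  equally.
* The LME path covers exactly one random intercept; no random slopes or
  crossed designs.
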