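---
title: "Stage-varying brain network analysis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-varying brain network analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models the package implements, the
assumptions behind them, the parameters that matter, and the places where
the design was genuinely open and a choice had to be made.

## The scientific setting

In neurodegenerative disease, grey-matter volume (GMV) and glucose
metabolism (FDG PET) do not decline voxel by voxel in isolation: they
covary across individuals in spatially coherent networks anchored at
characteristic regions (hippocampus, angular gyrus, posterior cingulate,
and so on). The package quantifies, per participant, how strongly each
such covariance network is expressed, and then asks whether the
association between network expression and memory performance is constant
across the disease continuum or varies with clinical stage — separately
within each CSF-defined pathology stratum (A−T−, A−T+, and the merged
amyloid-positive group A+).

## Seed definition

Seeds are found where *both* modalities show group-level differences
between cognitively normal and dementia participants. Per modality the
package computes a voxelwise two-sample t contrast (pooled variance,
one-sided: CN greater than dementia) after regressing age, gender,
education and APOE ε4 out of the pooled data; inference is by label
permutation on the residualised data (a Freedman–Lane-style scheme: the
nuisance fit is removed once, and exchangeability is assumed for the
residuals). Each permuted t map is enhanced with threshold-free cluster
enhancement (TFCE) and the maximum enhanced value per permutation forms
the null for family-wise-error-corrected voxel p values.

TFCE parameters are the published standard: extent exponent `E = 0.5`,
height exponent `H = 2`, face connectivity, and integration step
`dh = max(map)/100` recomputed per map. These are conventions, not fitted
values; the test suite pins the implementation to a brute-force
per-threshold cluster enumeration and to the closed form
`h^(H+1)/(H+1)` for an isolated peak as `dh → 0`.

The two thresholded t maps are summed voxelwise and, within a
configurable search neighbourhood around each expected region, the peak
of the summed map among significant voxels becomes a seed centre; seeds
are 4 mm spheres with membership by voxel-centre distance. The default
search radius is 12 mm: half the smallest distance between distinct
default loci is about 9 mm, and 12 mm tolerates noise-driven peak drift
while still guaranteeing that neighbouring regions (ANG and PPC, 18.3 mm
apart) cannot capture each other's peak — with a 16 mm radius they
occasionally did, producing duplicate seeds. A region whose neighbourhood
contains no significant voxel is reported absent, never fabricated.

## Seed partial least squares

For one seed and one modality, the seed value is the participant's mean
image value over the seed's voxels. With the seed vector and every voxel
column centred and scaled to unit Euclidean norm, the correlation vector
`R = Yᵀ X` holds exact Pearson correlations. Its SVD `R = v s uᵀ` has, in
the single-seed case, exactly one latent variable with the closed form
`u = Rᵀ/‖R‖`, `s = ‖R‖`, `v = 1`; the implementation goes through the
general SVD path and the test suite verifies the closed form to
`1e-10` on every synthetic run, which pins the normalisation conventions.

Significance is a permutation test on the subject order of Y relative to
X with the singular value as statistic, `p = (1 + #{s_perm ≥ s_obs}) /
(n_perm + 1)` — the estimate is never zero and never below
`1/(n_perm + 1)`. Voxel reliability is the bootstrap ratio: subjects are
resampled with replacement, each bootstrap salience is sign-aligned to the
original (PLS saliences are defined up to sign; without alignment the
bootstrap SE would be inflated by arbitrary flips), and the original
salience is divided by the voxelwise bootstrap SD. Degenerate resamples
(constant seed vector) are redrawn and counted.

Individual network scores are projections of the participant's raw voxel
vector onto the salience, `L_X = X u`. Left/right homologous seeds are
averaged on the raw projection scale *before* z-scoring: the z-transform
of an average keeps a single interpretable scale, whereas averaging two
z-scores would depend on each side's dispersion. (The alternative order is
defensible; this one is fixed and documented.) Scores are z-scored against
a reference group — all participants by default, the CN subgroup as a
robustness variant. Only the first latent variable is carried forward, and
only if its permutation p is at or below 0.05.

## Staging, stratification, group statistics

The diagnostic helper implements the screening rules (CN: MMSE ≥ 24 and
CDR 0; MCI: MMSE ≥ 24 and CDR 0.5; dementia: MMSE ≤ 26 and CDR ≥ 0.5).
Where MMSE 24–26 with CDR 0.5 satisfies both impaired rules the helper
returns MCI, because the dementia label additionally requires a clinical
judgement no score rule reproduces; records matching no rule are flagged
unclassifiable rather than defaulted. Pipelines with a curated diagnosis
column pass it through untouched.

Pathology strata use strict cutoffs (amyloid-positive iff
Aβ1-42 < 192 pg/mL; among amyloid-negatives, tau-positive iff
p-tau181 > 23 pg/mL). Amyloid-positive participants are never split by
tau status, matching how every downstream analysis treats them.

The pseudo-stage ordering is a total order: stage block (CN, MCI,
dementia — or CN versus pooled MCI+dementia under the `merged` strategy),
then MMSE descending within CN and CDR-SOB ascending within the impaired
block(s), then age ascending, then participant id. The final id tie-break
makes the order deterministic under any input permutation. Binning cuts
the order into `K = ceiling(n / bin_size)` contiguous bins with sizes
differing by at most one (larger bins first); with n divisible by the
default bin size of 10 this is exactly 10 per bin, and the near-even rule
is the natural reading of "evenly" when a remainder exists.

Group comparisons of network scores first regress out age, gender,
education, APOE ε4, intracranial volume and site, then run a permutation
one-way ANOVA (F statistic, labels permuted on the residualised scores)
and pairwise permutation t tests with Bonferroni–Holm correction over the
pair family. Post-hoc permutations act on the same residualised scores as
the omnibus test, keeping one exchangeability frame for the family.

## The sparse varying-coefficient model

Within a pathology group, with every variable z-scored (so no intercept),
memory is modelled as `y_i = Σ_j β_j(t_bin(i)) x_ij + ε_i` with each
coefficient function a cubic B-spline over the bin axis,
`β_j(t) = Σ_m γ_jm B_m(t)`. The clamped basis satisfies partition of
unity; its Gram matrix `Ω_mm' = Σ_k B_m(t_k) B_m'(t_k)/K` is the discrete
quadrature of `∫ β_j²(t) dt`, evaluated at the bins because the model
itself only lives at the bins.

**Penalty form.** The natural penalised objective couples the squared
loss with `λ Σ_j ∫ β_j²`, a quadratic that cannot set groups exactly to
zero — yet the procedure's purpose is variable selection. The package
therefore defaults to the group norm `λ Σ_j √(γ_jᵀ Ω γ_j)`, the group
lasso under the Ω metric, which zeroes whole coefficient functions, and
exposes the pure quadratic as `penalty = "ridge"` (useful as the
robustness variant: its dominant coefficient groups should coincide with
the group-lasso selection). This is the one place where the printed
objective and the described behaviour of the reference procedure point in
different directions, and the package resolves it in favour of behaviour,
keeping both forms available.

**Solver.** The substitution `γ̃_j = Ω^{1/2} γ_j` turns the penalty into
the Euclidean group norm, giving a standard group lasso solved by block
coordinate proximal descent in gram form (`G = Z̃ᵀZ̃/n`, `c = Z̃ᵀy/n`
computed once; each block step costs O(pM²)). Convergence is declared
when every Karush–Kuhn–Tucker residual — `‖c_j − (Gγ)_j‖ ≤ λ` for zero
groups, stationarity within tolerance for active groups — falls below
`1e-5` (checked every five sweeps; cap 10 000 sweeps, warning on
non-convergence). Warm starts along a decreasing λ path give monotone
active sets in practice; λ_max, from the KKT condition at the origin, is
`max_j ‖c_j‖`, and the default grid is 50 log-spaced points down to
`1e-3 λ_max`. The ridge variant solves its normal equations exactly, so
`λ = 0` reproduces unpenalised least squares — the solver's oracle test.

**Cross-validation and the 1-SE rule.** λ is chosen by fivefold
cross-validation with folds stratified by bin (each fold sees the whole
stage axis). The default selection is the one-standard-error rule: the
largest λ whose CV error is within one SE (across folds) of the minimum.
The plain minimiser systematically drags in a few spurious predictors —
with the data fixed and only fold assignments varying across repetitions,
those spurious inclusions repeat identically and would masquerade as
stable selections; the 1-SE rule is the standard conservative remedy and
makes the repetition frequencies informative. `rule = "min"` is available.

**Stability and specificity.** The CV + final fit is repeated 100 times
with fresh fold seeds; predictors selected in more than 90 repetitions
are kept. Curves are summarised by the pointwise mean and standard error
across repetitions (SE of the replicate mean, `sd/√n_rep`; the reported
band is mean ± 2 SE). Specificity permutes memory across participants and
reruns the whole procedure per permuted dataset; selection frequencies
under the null should carry no trace of the planted predictors.
Group-lasso shrinkage biases coefficient magnitudes toward zero, so
recovered curves are attenuated relative to truth; the selection decision
and the curve's shape are the reported quantities.

**Nuisance predictors** (gender, education, APOE ε4, ICV, effect-coded
site) enter the model exactly like network scores — penalised, with their
own stage-varying coefficients — rather than being residualised out, so
their stage-varying associations are themselves estimable.

## What the synthetic cohorts emulate

The generator plants, per region, a smooth Gaussian blob (bilateral where
the region is bilateral) whose subject loadings are
`Normal(μ_stage, loading_sd²)` with stage means declining 0.8 → 0 → −0.8
from CN to dementia; maps are `Σ_j loading_ij · pattern_j` plus a per-site
offset field and iid voxel noise. CSF values are drawn strictly inside
the cutoff intervals so the planted strata are recovered exactly; MMSE
and CDR are drawn consistently with the stage labels. Memory is generated
from the *true* loadings (standardised within pathology group) under
configurable coefficient curves — by default only the hippocampal
structural network carries signal, declining from 0.8 to 0.2 across bins
with residual SD 0.6, a moderate-noise regime in which the planted
association explains roughly a third of memory variance at the early
bins.

Numerical defaults: 24×24×24 grid at 4 mm (a compact stand-in for a
downsampled brain volume), pattern SD 7 mm and voxel noise SD 0.3 against
unit loading SD. These describe strongly expressed, spatially smooth
covariance networks — the regime of smoothed GMV/FDG maps, where spatial
smoothing has already suppressed independent voxel noise — and were fixed
once so that pattern recovery is achievable at the desk-scale sample
sizes the tests use (about 400 participants), mirroring the clearly
significant, highly reliable network patterns the method is designed for.
Because all networks share the stage gradient, any two network loadings
correlate (about 0.3 at the defaults) — deliberately so: it reproduces
the real difficulty that every disease network tracks severity, and it is
why the salience-recovery tests compare against the model-implied
correlation map (closed form under the generator) rather than against a
single region's blob.

What the cohorts do *not* emulate: anatomy, registration error,
partial-volume effects, spatially correlated noise, site-by-disease
interactions, longitudinal change, or item-level psychometrics. Passing
tests demonstrate that the algorithms recover known truth under the
stated generative model, not that the pipeline is robust to every
real-data pathology.

## Problem sizes used by the tests

The test suite and the acceptance script run at sizes a workstation
handles in minutes: seed definition on 30 participants per contrasted
group with 500–1000 permutations; calibration studies with 200–500 null
replicates at 199 permutations each; the regression stage at its full
design size (300 participants per pathology group, 30 bins, 100
repetitions) over a reduced 20-point λ grid; specificity at 20 permuted
datasets × 20 repetitions. The reference parameterisation (5000/1000/500
permutations and bootstraps, 50-point grid) is the package default
throughout; the reduced sizes are choices of the test harness, stated in
each test.

## Known limitations

- Single-seed PLS only: one latent variable per seed-modality analysis;
  multi-seed (block) decompositions are out of scope.
- No pointwise inference on coefficient curves (no per-bin p values); the
  ±2 SE band describes repetition stability, not sampling uncertainty.
- The pseudo-stage axis is cross-sectional ordering, not time; bins mix
  participants, and the model's "trajectory" is a population statement.
- Permutation tests assume exchangeability after residualisation;
  structured dependence (family, scanner batches beyond the site factor)
  would violate it.
- The diagnostic helper cannot reproduce clinical judgement; it exists
  for synthetic data and sanity checks, not to re-diagnose cohorts.
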