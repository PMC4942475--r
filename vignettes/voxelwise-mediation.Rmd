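---
title: "Voxel-wise serial mediation: model, inference, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise serial mediation: model, inference, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxmed)
```

## The scientific question and the model

Older adults pay a larger time penalty when switching between tasks. The
question this package operationalizes is whether that group difference runs
through the brain: age group may lower regional gray-matter volume, altered
volume may change task-related activation, and altered activation may change
performance. With group `A` (0 = young, 1 = old), voxel gray-matter volume
`S`, voxel activation `F`, and the global switch cost `P` in seconds, four
OLS regressions are fit at every voxel of an analysis mask:

$$P = cA + \varepsilon_1,\qquad
  S = aA + \varepsilon_2,\qquad
  F = bS + dA + \varepsilon_3,\qquad
  P = eF + fS + c'A + \varepsilon_4 .$$

Sex and normalized whole-brain volume (nWBV, the intracranial brain
fraction (GM+WM)/(GM+WM+CSF)) enter **every** equation, including the first
two. Applied literally, this guarantees the algebraic decomposition

$$c = c' + a\,f + d\,e + a\,b\,e$$

holds exactly at every voxel — not approximately — because the four fits are
nested OLS projections of the same sample with the same covariate block. The
test suite asserts this identity to a relative 1e-10 on random data; it is
the package's central internal consistency check. The three products are the
indirect effects (through structure, through function, and through the
structure→function chain); `%IND` expresses each as a signed percentage of
the total effect, so a negative value marks inconsistent mediation
(suppression).

The model is causal only by assumption: the data are cross-sectional and the
ordering structure → function → performance is imposed, not tested.

## Fitting

Group coding is fixed at young = 0, old = 1 so a positive total effect means
worse (larger) switch costs in old age. Covariates are z-scored before
entering the design — this stabilizes conditioning and leaves the `A`, `S`,
`F` coefficients unchanged. Subjects with any missing analyzed field are
dropped (complete cases), with a message.

Voxel-wise fitting residualizes `A`, `P`, and the map matrices on the shared
covariate block once (Frisch–Waugh–Lovell) and then solves the per-voxel
2×2 and 3×3 normal equations in closed form, vectorized over voxels. This
reproduces full-design OLS exactly — a per-voxel `lm()` oracle agrees to
1e-10 in the tests — and makes a permutation refit a handful of matrix
products, since only the group labels change. Rank deficiency (e.g. a
constant map at a voxel) and non-finite in-mask values raise errors naming
the voxel.

The analysis mask requires (i) a supra-threshold activation effect in at
least one group — two-tailed uncorrected one-sample t at α = 0.05, each
group against its own df — and (ii) gray-matter probability above 0.5. Both
thresholds are arguments.

## Inference

Significance of the indirect-effect maps uses the 'single threshold'
(max-statistic) permutation test with threshold-free cluster enhancement:

1. Each indirect-effect map is z-standardized per voxel by the mean and SD
   of its permutation distribution. Products of coefficients have strongly
   voxel-varying scale, and a max statistic is only meaningful on comparable
   units. The raw-product alternative is exposed (`statistic = "raw"`).
2. The positive parts of `z` and `−z` are TFCE-enhanced separately
   (defaults E = 0.5, H = 2, step = map max/100, 26-connectivity — the
   method's standard volumetric settings, all exposed).
3. For each of `m` permutations (study default 2000) the group labels are
   randomly shuffled, the full model refit, and the in-mask maximum enhanced
   statistic recorded per tail. Corrected p at a voxel is
   `(exceedances + 1)/(m + 1)` on the voxel's tail, ties counting as
   exceedances; two-tailed control allocates α/2 per tail.
4. A voxel is reported significant when corrected p ≤ α/2 on its tail
   **and** |%IND| ≥ 5 (the effect-size screen; configurable, 0 disables).

Permutation `r`'s shuffle derives from a deterministic function of the
master seed and `r`, so results are reproducible and independent of
evaluation order; identical seeds give bit-identical p maps. With small `m`
the engine warns when the p-value floor `1/(m+1)` cannot reach α/2. An
exhaustive mode enumerates all distinct group-label assignments for small
samples and then reports exact enumeration p-values; the test suite compares
it against a brute-force oracle (per-voxel `lm()` fits, naive threshold-loop
TFCE, explicit enumeration of all 252 relabelings of a 10-subject dataset)
and requires exact agreement.

### Why the standardization moments include the observed statistic

The z-standardization must be a symmetric function of the whole set
{observed, permutations}. If the moments come from the permutations only,
each permuted value is shrunk by its own leave-in contribution to the SD
while the observed value is not; the `m + 1` enhanced statistics are then
not exchangeable and the test is anti-conservative (the effect is large at
desk-scale `m`, where the SD estimate is noisy and the image-wide maximum
selects voxels with underestimated SD). With the observed statistic included
the set is exchangeable under the null, and the suite verifies the level
empirically: on data where group labels carry no information at all, the
fraction of null datasets with any corrected p ≤ α/2 stays at or below the
nominal level.

### What simple label shuffling can and cannot null out

The permutation scheme shuffles the raw group labels, exactly as stated for
the original analysis. This is correct under full exchangeability, but when
the group has a *real* direct effect on performance (here c ≈ 0.08 s) or a
real association with a covariate (old-group nWBV runs lower), shuffling
destroys those nuisance relationships too: the unabsorbed `c·A` component
leaks a voxel-specific offset into the permuted e-path null, and observed z
maps become overdispersed relative to the permutation null. The acceptance
suite therefore measures two things, both computed by
`scripts/acceptance.R` and the tests rather than asserted:

- the level of the *permutation machinery itself* under a fully exchangeable
  null (no group differences anywhere), which is exact; and
- the family-wise false-positive rate of the *full pipeline* — corrected p
  **and** the ≥5 %IND screen — on null simulations at the study's group
  structure (real total effect, unequal variances, shifted nWBV, no planted
  voxel effects), which stays within the binomial band around α = 0.05. The
  %IND screen is what makes the pipeline robust here: label-shuffling
  leakage produces significant voxels whose indirect effects are tiny
  relative to the total effect, and the screen removes them.

Covariate-respecting permutation schemes (residual-based) would address the
leakage at the level of the statistic; they are deliberately out of scope
and the simple scheme is retained as the method under study.

### FWE is controlled per pathway

Each of the three indirect-effect maps is corrected for multiple comparisons
separately (its own null max distribution), matching how the original
tables report one pathway per table. "Any significant voxel" in the FWE
checks therefore refers to one pathway's map; controlling across the three
pathways jointly would require a max over pathways and is not claimed.

## TFCE numerics

The enhanced value at voxel `p` is
$\sum_h e(h)^{E}\, h^{H}\, \mathrm{d}h$ over thresholds
`h = dh, 2dh, …`, where `e(h)` is the voxel count of the connected
component containing `p` in the supra-threshold set at `h`. Components are
labeled by flood fill in C++ (6/18/26-connectivity). Two numerical choices
matter and are tested:

- Thresholds are computed as `max·k/n_steps` with an integer counter, never
  by accumulating `h += dh`, and the top threshold is pinned to the map
  maximum itself — `(max·k)/n_steps` can round one ulp above the maximum and
  silently drop the final integration step, which is a 1–2% error that
  breaks exact agreement with an independent implementation.
- Tie counting in the max-statistic comparison uses a small (1e-9) relative
  tolerance. Mathematically tied enhanced statistics occur structurally —
  the complement of a relabeling mirrors its indirect-effect maps exactly —
  and must be counted as ties regardless of floating-point evaluation order.

The suite checks convergence to analytic values (an isolated unit peak
integrates to 1/3 at E = 0.5, H = 2; a two-voxel plateau to √2/3 per voxel),
monotonicity in the input, zero outside the mask and on non-positive values,
and exact agreement with a naive threshold-loop oracle.

## The synthetic-data generator

The generator emulates the study conditions: 63 young and 112 old subjects;
global switch costs with group means 0.22/0.30 s and SDs 0.083/0.15 s
(truncated at zero); sex Bernoulli(½); nWBV Gaussian with the old group's
mean 5% lower (a monotone-with-age covariate, magnitude configurable);
16³ grids of 2 mm voxels; an ellipsoidal gray-matter envelope at
probability 0.9 inside / 0.1 outside, exercising the 0.5 mask threshold; and
designated signal regions carrying planted path coefficients, the default
being an 8-voxel (2×2×2) cube with a = −0.5, b = 0.4, d = 0.2, e = 0.3,
f = 0.1, c′ = 0.13 — so the serial indirect effect is a·b·e = −0.06 and the
implied total effect c = 0.08 matches the behavioral group difference.

Design choices a user should know:

- **Noise is smoothed; signal is not.** Voxel noise is drawn independently
  and Gaussian-smoothed at 8 mm FWHM — smoothing exists to induce the
  spatial correlation TFCE exploits — and the planted signal is added
  afterwards, so every in-region voxel carries the planted coefficients
  exactly. Smoothing the signal too would dilute voxel-level coefficients
  toward region edges and leave "the true voxel effect" undefined. (The
  original acquisition describes the smoothing kernel as 8 mm FWHM in one
  place and 8 mm³ in another; 8 mm isotropic is used.)
- **Mediators need subject-level variation.** Beyond smoothed voxel noise,
  each signal region receives per-subject scatter in `S` and `F`
  (`subject_sd_S`, `subject_sd_F`): individual differences in regional
  volume and activation not explained by group. This is what identifies the
  b, e and f paths in real data; with voxel noise alone, mediator variation
  conditional on group would be nearly zero and those paths would be both
  unrealistic and ill-estimated.
- **Performance is tied to region means.** `P` is regenerated as
  `e·F̄ + f·S̄ + c′·A + covariates + noise` with `F̄`, `S̄` the subject's
  means over the primary region, so the planted pathway is exactly
  consistent with the maps. The printed cost SDs act as residual scales in
  that case. Because the fit uses single-voxel `F`, not `F̄`, the voxel-level
  e estimate carries a small errors-in-variables attenuation; with the
  default smoothness and an 8-voxel region the within-region noise is highly
  correlated and the attenuation of the recovered a·b·e is a few percent —
  measured, not assumed, by the recovery check.
- A noise-free generator run cannot make *all* path estimates exact
  simultaneously: zero residual in the F-equation makes `F` an exact linear
  combination of `S` and `A` and the P-equation rank-deficient. The
  machine-precision recovery test therefore constructs its voxel with
  residuals orthogonalized in-sample; generator-based recovery is covered by
  a convergence property in which the noise scales vanish at staggered rates
  (mediator scatter ~ √σ, map noise ~ σ, cost residual ~ σ^1.5) so that each
  equation's residual shrinks faster than its regressors' exogenous
  variation.

What passing synthetic checks do **not** show about real data: the generator
has no MRI physics, motion, registration error, or spatially varying
smoothness; its gray-matter envelope is a cartoon; its planted effects are
homogeneous within a region; and no voxel-level effect sizes are published
for the original data, so the generator's SNR is chosen for testability, not
realism. Conclusions about power or %IND magnitudes on real data do not
transfer.

## Problem sizes used by the tests and acceptance script

Decomposition exactness: 50 random datasets, 16³ grid, n = 30. Exhaustive
oracle: 10 subjects, 4³ grid, all 252 relabelings. FWE: 200 null simulations
at 12³, n = 40, m = 99 (the p-value floor 1/100 comfortably reaches α/2;
with m = 99 the finest achievable per-tail level is 0.02, so even an exact
test lands near 0.04 two-tailed rather than 0.05). Recovery/power: 100
fit-only and 20 full-inference simulations at the study's n = 175 on 16³
grids. These sizes keep a full run in minutes on one CPU while leaving each
check statistically meaningful; all seeds are fixed in the tests and derived
from `--seed` in the script.

## Known limitations

- Simple label shuffling with a real direct effect is anti-conservative
  without the %IND screen (measured and documented above); residual-based
  schemes are not implemented.
- Anatomical labeling (region names, Brodmann areas) is out of scope; tables
  carry mm coordinates only.
- Bootstrap confidence intervals for indirect effects, cluster-extent
  correction, FDR, and standardized effect sizes are non-goals.
- The covariate-adjusted behavioral effect printed for the original cohort
  (β = 0.067, t(171) = 2.21) depends on subject-level covariates that were
  never released; the pipeline computes the same quantity on its own data
  but the published number is not reproducible from summaries.
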