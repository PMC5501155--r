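---
title: "Presence-only maximum-entropy habitat modeling with maxhab: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Presence-only maximum-entropy habitat modeling with maxhab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`maxhab` implements a complete presence-only habitat-suitability workflow
for a species observed at known locations on a landscape described by
aligned raster layers. This vignette explains the statistical model, the
procedural choices around it, the knobs that matter, what the synthetic
validation landscapes do and do not demonstrate, and the package's known
limitations.

## 1. The estimation problem

Presence-only data tell us where a species *was seen*, not where it is
absent. The maximum-entropy approach treats the landscape itself — a
sample of `m` *background* cells — as the reference distribution and asks
for the distribution `q` over those cells that is as close to uniform as
possible while matching the environmental feature averages observed at
the `n` presences. The solution is a Gibbs distribution

    q(x) = exp(sum_j lambda_j f_j(x)) / Z,

and the coefficients are found by maximizing the penalized presence
log-likelihood

    (1/n) sum_i eta(x_i) - ln Z - sum_j beta_j |lambda_j|,

where `eta = sum_j lambda_j f_j`. The **regularized gain** reported with
every fit is this objective plus `ln m`, i.e. the penalized likelihood
improvement over the uniform model; zero means the presences look like a
uniform draw from the background.

### Features

Each continuous variable is clamped to its background range and rescaled
to `z` in [0,1]. The expansion then contains `z` (linear), `z^2`
(quadratic), pairwise products, and one-sided hinge ramps
`max(0, (z - t)/(1 - t))` at `hinge_knots = 50` evenly spaced background
quantiles `t`. Signed combinations of one-sided hinges span all continuous
piecewise-linear response shapes with those knots (up to an additive
constant, which a Gibbs model cannot see), so a second reversed hinge
family would be redundant. Categorical variables expand to one indicator
per class code and never enter correlation screening. Which classes are
used follows the presence count: `< 10` linear only, `>= 10` adds
quadratic, `>= 15` hinge, `>= 80` product — the conventional sample-size
ladder for this model family.

### Regularization

The per-feature penalty is `beta_j = r * s_j / sqrt(n)` with `s_j` the
presence-sample standard deviation of feature `j` (floored at 1e-4) and
`r` the regularization multiplier (default 1). This keeps the classical
`O(1/sqrt(n))` scaling — more presences allow more complex responses —
with a single interpretable multiplier instead of per-class lookup
tables. A consequence worth knowing: hinge features get lighter penalties
than a per-class table would give them, so fitted responses can be
wigglier than classical MaxEnt output at the same `r`.

### Solver

The objective is concave. It is maximized by an accelerated proximal
gradient method (FISTA) with backtracking line search and adaptive
restart; the soft-thresholding step produces exact zeros. Convergence is
declared at relative objective change below `tol = 1e-5`, capped at
`max_iter = 500` iterations.

After FISTA, the solution is *polished* by coordinate-wise proximal-Newton
steps plus a "zero-cost zeroing" pass: with 50 hinge knots per variable,
neighbouring feature columns are nearly collinear, the optimum is
degenerate, and the accelerated-gradient path tends to spread small
weights across many equivalent features. The polish accepts a coordinate
update only when the exact penalized objective improves, then removes any
coefficient whose deletion does not change the objective (within 1e-10).
This deterministically selects the sparsest member of the optimal set —
important because the nonzero-coefficient count `k` feeds the AICc below;
without it, `k` measures solver history rather than model complexity.

### Outputs

*Raw* output is `q` itself (sums to 1 over the background). *Logistic*
output is `q e^H / (1 + q e^H)` with `H` the entropy of `q`: a monotone
rescaling to a 0–1 suitability index in which a cell whose conditions
match a typical presence scores about 0.5. By default the presence rows
are appended to the background for normalization (`presences_in_background
= TRUE`), the standard convention; the closed-form unit tests disable it.

## 2. Occurrence thinning

Records closer than twice the buffer radius have overlapping home-range
buffers. The overlap graph is cut into connected components
(single-linkage, so chains A–B–C collapse even when A and C are far
apart), and exactly one record per component is kept, chosen uniformly at
random. Two properties follow: the retained count is independent of the
seed, and no two retained records are closer than twice the radius. The
default radius 564.19 m is the radius of a circle of area 1 km² — the
package reads "a 1 km² buffer" as a circular buffer of that area; since a
1-km *radius* is the other defensible reading, the radius is a config
value (`thin_radius`), and the pseudo-absence exclusion radius
(`pa_exclusion_radius`, default 1000 m) is configured separately.

## 3. Stepwise variable selection by AICc

Step 1 fits all variables. At step `t`, the screening variable `v*` is
the `t`-th highest contributor of the current model (ties broken by
name); every other variable with contribution `< 1%` or Pearson
`|r| > 0.7` against `v*` (computed on the shared background sample) is
removed and the model refitted. The loop ends when the rank exceeds the
remaining variable count or no further rank removes anything. One
background sample is shared by all candidate fits, so AICc differences
reflect variable sets, not sampling noise.

Percent contribution is computed by deterministic leave-one-variable-out
refits: `drop_v = max(0, gain_full - gain_without_v)`, normalized to sum
to 100. This replaces the path-dependent per-iteration attribution of the
original implementation with an optimizer-agnostic, reproducible
quantity. Caveat: a variable and a strong correlate can partially
compensate for each other, deflating both drops — which is precisely why
the correlation rule, not the contribution rule, is the intended remover
of duplicates.

AICc uses the landscape-standardized likelihood: raw output is
renormalized to sum to 1 over all unmasked study-grid cells, `lnL` is the
sum of log standardized raw values at the presence cells, `k` counts
nonzero coefficients, and

    AICc = 2k - 2 lnL + 2k(k+1)/(n-k-1),

flagged invalid when `k >= n - 1` and then excluded from winner choice.
The ambiguity of ranking "the second highest contributed variable" against
model 1 or model 2 is resolved as *current model* by default
(`rank_from = "current"`); `"initial"` freezes the full-model ranking.

## 4. Evaluation

"Bootstrap" replicates are independent 75/25 presence splits without
replacement (train count = `round(0.75 n)`); a resample-with-replacement
mode is available (`replicate_mode = "bootstrap"`) but the split matches
the 75%-training / 25%-test description of the workflow this package
follows. AUC is the Mann–Whitney rank statistic of presences against the
*background* sample (the model's own reference set); maximized Kappa and
TSS score the *test* presences against 200 fixed pseudo-absences drawn
once, uniformly over unmasked cells at least 1 km from every presence.
Thresholds are scanned on the grid 0, 0.001, …, 1 with "score >=
threshold means predicted presence", and the smallest threshold attaining
the maximum is reported, so results are deterministic. Verbal labels use
the conventional bins (AUC: excellent above 0.9, then good/fair/poor,
failed below 0.6; Kappa: excellent above 0.75, good above 0.4; TSS: good
to excellent above 0.8, useful above 0.5), with boundary values assigned
upward.

The final habitat map averages the 20 replicate logistic grids cell-wise
and binarizes at the threshold maximizing TSS *of the averaged map*
(thinned presences vs the pseudo-absences). Averaging first and
thresholding once is a single well-defined rule; the per-replicate mean
TSS threshold is also reported for comparison.

## 5. Habitat accounting

Cells are assigned to a zone when their center lies inside the polygon
(even-odd rule, via `mgcv::in.out`); overlapping zones each count shared
cells, but the protected fraction uses the cell-wise *union* of reserves
so nothing is double-counted. Percentages are reported at two decimals
with half-up rounding, matching how such gap tables are conventionally
printed. The cell-center rule is deterministic but resolution-limited:
zone areas can differ from exact polygon-clipped GIS areas by up to about
one cell per boundary cell; the package's own invariants (partition sums,
monotonicity under threshold increase) are exact because its test zones
follow cell edges. Patch statistics use 8-connectivity by default
(diagonally touching ridgeline cells connect; 4-connectivity available).

## 6. The synthetic landscape generator

Validation needs landscapes where the truth is known. The generator
builds standardized Gaussian random fields (white noise convolved with a
row-normalized separable Gaussian kernel; `length_scale` defaults to
2500 m, i.e. 10 cells) and plants responses on them:

* **gaussian(mu, sigma)** — unimodal suitability
  `exp(-(v-mu)^2 / 2 sigma^2)`, the narrow-envelope shape typical of
  climatic limits;
* **saturating(d0)** — `min(1, v/d0)`, the increasing shape typical of
  distance-to-disturbance variables;
* **flat** — no effect.

The truth is the *product* of the factors: independent environmental
filters, which yields unimodal marginal responses of the kind the model's
response curves should recover. Duplicates are `r X + sqrt(1-r^2) E`
with `E` a fresh field residualized against `X`, so the realized all-cell
correlation equals the target exactly. Presences are sampled without
replacement with probability proportional to the truth and placed at cell
centers — mirroring a one-record-per-cell, post-thinning data structure.

Default configuration (the package's self-validation condition): a
200 x 200 grid at 250 m (a 50 km square), two informative variables with
`sigma = 0.3` in standardized field units, one duplicate at `r = 0.9`,
three noise layers, and 150 presences. `sigma = 0.3` makes the planted
niche a narrow environmental band — the strongly structured truth of a
habitat specialist, which is the regime this workflow targets; with a
diffuse truth (`sigma` near 1) presences resemble background and no
method recovers much.

What passing recovery shows: on landscapes with smooth fields, planted
low-dimensional truth and unbiased sampling, selection keeps the planted
variables and drops redundant duplicates (90% of 20 seeds in the shipped
acceptance run), response-curve peaks land within half a planted standard
deviation of the optimum (median), and test AUC exceeds 0.9. What it does
*not* show: robustness to sampling bias, spatial sorting of survey effort,
misaligned or error-laden rasters, non-multiplicative niche structure, or
temporal nonstationarity — all present in real data and all outside the
generator.

## 7. Problem sizes and numerical details

Self-validation runs use a background sample of 2000 cells (of 40 000)
rather than the 10 000-point default: at 200 x 200 the background then
still covers 5% of the landscape, and candidate fits across 20 seeds stay
desk-scale. Bootstrap evaluation runs on 5 of the 20 recovery seeds (100
replicate test AUCs in total) and response curves on 10; selection runs
on all 20. Unit tests use 30–60-cell grids.

Other numerical choices: features are clamped to the training background
range before prediction, so projection never extrapolates features
outside [0,1]; hinge knots are quantile-based, so duplicate knots can
arise in ties and are kept (harmless under L1); constant layers are
dropped from the expansion with a warning; correlation screening excludes
constant columns; `Pe = 1` defines Cohen's kappa as 0; contribution ties
break lexicographically; thresholds tie-break to the smallest maximizer;
the overlap relation in thinning is strict (`distance < 2r` merges), so
retained sets satisfy `distance >= 2r` exactly. Grid cell ownership is
half-open: points on shared edges belong to the right/lower cell. All
stage seeds are derived deterministically from one master seed and the
stage name, and every generator is a pure function of its configuration,
so identical configs give byte-identical results.

## 8. Known limitations

* No reprojection or resampling: all layers must already share one grid.
  Raster I/O is plain-text ESRI ASCII grids.
* Distances are planar Euclidean on projected coordinates; no geodesic
  support.
* Threshold features, cloglog output and extrapolation diagnostics (MESS)
  are not implemented.
* Zonal areas use the cell-center rule, not polygon clipping.
* The AICc parameter count equals the number of nonzero coefficients,
  which remains a convention rather than a true effective dimension; the
  solver's sparsification makes it stable, not exact.
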