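# maxhab

Presence-only habitat suitability modeling for gridded landscapes:
a maximum-entropy (MaxEnt-style) species distribution model wrapped in the
full workflow a conservation study needs — occurrence thinning, stepwise
variable selection by AICc, replicated evaluation with AUC / maximized
Kappa / maximized TSS, max-TSS binary habitat mapping, and protected-area
gap analysis — plus a synthetic-landscape generator so the whole pipeline
can be validated by parameter recovery without any external raster
downloads.

The package is written for spatial ecologists who have presence records
(e.g. sightings of a rare montane bird) and a set of aligned environmental
raster layers, and who want a transparent, scriptable, fully reproducible
version of the familiar MaxEnt-plus-GIS workflow.

## The model

Given presences \(x_1,\dots,x_n\) and \(m\) background cells, the habitat
model is the Gibbs distribution over background cells

\[
q_\lambda(x) = \frac{e^{\sum_j \lambda_j f_j(x)}}{Z_\lambda},\qquad
Z_\lambda = \sum_{x \in \text{bg}} e^{\sum_j \lambda_j f_j(x)},
\]

whose coefficients maximize the L1-penalized presence log-likelihood

\[
\frac{1}{n}\sum_i \sum_j \lambda_j f_j(x_i) \;-\; \ln Z_\lambda
\;-\; \sum_j \beta_j |\lambda_j|,
\qquad \beta_j = r\, s_j / \sqrt{n},
\]

with features \(f_j\) the linear, quadratic, product, hinge and
category-indicator expansions of the environmental variables (each clamped
and rescaled to \([0,1]\)), \(s_j\) the presence standard deviation of
feature \(j\) and \(r\) the regularization multiplier. The reported
**regularized gain** is this objective plus \(\ln m\) (improvement over the
uniform distribution); the **logistic output**
\(q e^H / (1 + q e^H)\) (with \(H\) the entropy of \(q_\lambda\)) rescales
the raw density to a 0–1 suitability index.

Around the model:

* **Thinning** — records whose 1-km² home-range buffers overlap are grouped
  into connected components and one random representative per component is
  kept.
* **Variable selection** — starting from all variables, each step removes
  variables contributing < 1 % or with Pearson |r| > 0.7 against the
  current t-th top contributor, refits, and scores each candidate by
  \(\mathrm{AICc} = 2k - 2\ln L + 2k(k+1)/(n-k-1)\), with \(\ln L\) from
  the landscape-standardized raw output and \(k\) the number of nonzero
  coefficients. Lowest valid AICc wins.
* **Evaluation** — 20 bootstrap replicates of a 75/25 presence split;
  training/test AUC against the background, maximized Cohen's kappa and
  TSS against 200 pseudo-absences drawn outside 1-km presence buffers.
* **Habitat accounting** — replicate-averaged suitability, binarized at the
  max-TSS threshold; areas, per-zone (county / nature-reserve) summaries by
  the cell-center rule, protected fraction over the cell-wise reserve
  union, and patch fragmentation statistics.

## A worked example

```r
library(maxhab)

# a synthetic 50 x 50 km landscape with two informative variables
# (planted Gaussian responses), one correlated duplicate and three
# noise layers; 150 presences sampled from the truth
ds <- build_landscape(landscape_config(seed = 20170706))

report <- run_pipeline(ds$stack, ds$occurrences,
                       config = pipeline_config(n_background = 2000,
                                                seed = 20170706))
print(report)
```

```
run_report: 150 -> 73 occurrences after thinning
  selected: env_a, env_b, noise_1, noise_2
  train AUC 0.923 (excellent), test AUC 0.891 (good), kappa 0.571, TSS 0.787
  threshold 0.275 -> 648.6 km2 suitable in 12 patches
```

Reading the output: thinning merged records whose 1-km² buffers overlapped
(150 → 73); the AICc winner kept both planted variables and discarded the
redundant duplicate (two weakly contributing noise layers slipped through
on this seed — selection recovers the planted pair and drops the duplicate
in ~90 % of seeds, see the recovery harness); the averaged 20-replicate
model separates presences from background with test AUC ≈ 0.89;
binarizing the averaged suitability at its max-TSS threshold (0.275)
yields ~649 km² of suitable habitat in 12 patches.

The published-table arithmetic is available directly: with the shipped
county/reserve area table for the Chinese monal in the Qionglai Mountains,

```r
za <- monal_zone_areas()
zone_proportion(146, 325)    # Heishuihe reserve:      44.92 (%)
zone_proportion(1364, 2490)  # protected fraction:     54.78 (%)
zone_proportion(2490, 26258) # of the whole region:     9.48 (%)
```

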