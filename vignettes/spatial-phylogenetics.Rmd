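---
title: "From occurrence points to phylogenetic diversity and endemism maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From occurrence points to phylogenetic diversity and endemism maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloscape)
```

phyloscape maps how a community's evolutionary history is distributed in
space. Starting from sparse, spatially biased occurrence records of a set of
related species — the motivating case is a community of about twenty
scolopendrid centipede species along a tropical mountain chain — it builds
per-species distribution models, converts them into a coarse
presence–absence grid, and computes per-cell diversity and endemism indices
on a dated phylogeny, together with null-model significance, compositional
turnover, and bioregion maps. This vignette documents the model choices,
their assumptions, the tunable parameters, and what the synthetic test
worlds do and do not demonstrate.

## The distribution model

True absences are unknowable for cryptic, low-abundance soil fauna, so each
species is modelled with a presence–background approach: the environment at
occurrence points is contrasted with a background sample of the available
environment. We fit the standard exponential (Gibbs) model: with feature
vector $f(x)$ for environment $x$ and coefficients $\beta$, the probability
that a presence falls at background location $i$ is

$$P(i) = \frac{e^{\beta^\top f(x_i)}}{\sum_j e^{\beta^\top f(x_j)}},$$

and $\beta$ maximizes the presence log-likelihood under a per-feature L1
penalty $\lambda_j = \mathrm{rm} \times \mathrm{base}_j / \sqrt{n}$, with
$n$ the presence count, `rm` the regularization multiplier, and base
constants 1 for linear/quadratic features, 0.5 for hinges and 0.25 for
categorical indicators. Optimization is by proximal gradient (FISTA) with
soft-thresholding and backtracking; the presence locations are included in
the background sample, which keeps the penalized likelihood bounded even
when presences are separable from the background in feature space. A fit
whose objective cannot be stabilized raises an error naming the settings;
in practice the penalty makes the problem strongly concave enough that this
does not occur. Duplicate background draws of the same raster cell are
collapsed into count weights before optimization — an exact reformulation
that makes a 10,000-point background sample as cheap as its number of
distinct cells.

Features come in six class combinations (LQH, LQ, QH, L, Q, H): linear
terms, squares, and forward/reverse hinge ramps at ten equally spaced
quantile knots per covariate per direction (Maxent's default of 50 knots is
excessive on desk-scale grids with few distinct values; the count is
configurable). All features are standardized by training mean and sd, and
zero-variance features keep a coefficient of exactly zero. Predictions are
normalized over the training background and mapped to $[0,1]$ by the
cloglog transform $1 - \exp(-e^H \cdot \mathrm{raw})$, with $H$ the entropy
of the background distribution; a logistic output is available.

### Background, bias, and evaluation

Sampling effort is rarely uniform, so background points are drawn (10,000
by default, with replacement, probability proportional to a bias layer)
from a surface fitted to the pooled occurrences of *all* species with
default settings (LQH, rm = 1) against a uniform background: environments
that were surveyed more are represented more in the background, which
prevents the per-species models from mistaking survey effort for habitat
preference.

Model settings are tuned per species over 6 feature classes × 10
regularization multipliers (0.5–5.0). Evaluation is geographically
structured: species with ≥ 20 presences are split into four spatial blocks
at the presence median longitude and latitude, with the background masked
to the same blocks; species with fewer presences use leave-one-out folds
with the full background. Per fold we record the omission rate of test
presences under the minimum-training-presence threshold (OR_MTP, strict
inequality: a test presence exactly at the threshold is not omitted), the
test AUC against the fold's background, and the train–test AUC difference.
Candidates with mean test AUC above 0.6 are compared sequentially —
minimum OR_MTP, then minimum AUC difference, then maximum test AUC —
with residual ties resolved toward the simpler feature class (H, Q, L, QH,
LQ, LQH) and the stronger penalty, so selection is deterministic and
order-independent. If no candidate clears the AUC filter the full set is
used with a warning rather than aborting a community-level analysis.

### From suitability to presence–absence

Continuous suitability at the fine grain is aggregated to the coarse
analysis grain (factor 100 at the original scales, 0.0083° to 0.83°; factor
4 in the synthetic worlds) by block *maximum* — a cell is suitable if any
of its subcells is. The maximum-sensitivity-plus-specificity threshold is
then computed from the coarse values at presence cells versus background
cells (fine-scale scores are available by option), with `>=` counting as
presence and ties resolved toward the smallest maximizing candidate
threshold. Two degradation paths replace the model by the rasterized raw
presence points: an explicit per-species override list, and an automatic
one when the selected model retains no nonzero coefficient — such a model
predicts a constant map, i.e. the species everywhere, which is the
overprediction failure mode that motivated the same fallback in field use.
Species with no occupied cell after cropping to the region polygon (cell
centres inside a WKT ring) are dropped with a warning, and range sizes are
recomputed on the cropped extent (the pre-crop alternative is a flag).

## Indices

On the resulting cells × species matrix with range sizes $R_i$ and a rooted
dated tree with branch lengths $L_b$ (total $L_{tot}$), each cell gets:

* **TD** — species count;
* **WE** — $\sum_i 1/R_i$ over the species present (summed over all cells
  this is exactly the species count, a conservation law used as a test);
* **PD** — total branch length of the minimum spanning path connecting the
  cell's species to the root, divided by $L_{tot}$ (range 0–1);
* **PE** — as PD with each branch divided by its range $R_b$, the number of
  cells occupied by at least one descendant tip (cell-wise sum equals the
  species pool's PD exactly);
* **RPD / RPE** — the ratio of PD (PE) to the same index on an identical
  topology with every branch length set to 1. Because both numerator and
  denominator are scaled by their own total tree length, any constant
  branch length gives the same ratio, so unit lengths lose no generality.
  Values above 1 mark assemblages dominated by long (old) branches.

Empty cells propagate as missing for the phylogenetic indices (never 0/0).
Null significance comes from the curveball (trial-swap) algorithm: matrices
are randomized holding every cell's richness *and* every species' range
size fixed, with burn-in of five times the matrix fill and one fill between
saved replicates; a matrix admitting no swap is returned unchanged with a
warning. Percentile ranks use the midrank convention,
$100\,(\#\{null < obs\} + \tfrac12 \#\{null = obs\})/n_{iter}$, flagged
high/low beyond 97.5/2.5. Because richness is fixed by construction, TD has
no null distribution — asserting this guards against implementing the wrong
null.

Turnover uses the Simpson dissimilarity $\min(b,c)/(\min(b,c)+a)$ and its
branch-length analogue (PhyloSor turnover) with shared and unique spanning
path lengths in place of shared and unique species; both ignore nestedness
by construction, and on a star tree with equal branch lengths the two are
identical. Occupied cells are clustered by UPGMA (average linkage) cut at
k = 4 by default, and coloured by the first three positive principal
coordinate axes of the dissimilarity matrix rescaled to RGB, so that
similar assemblages receive similar colours; "principal components of a
dissimilarity matrix" is only well-defined through double-centering, hence
PCoA (a raw-matrix PCA flag exists for figure mimicry). Missing axes (rank
< 3) fill their channels with 128.

## Synthetic worlds

The generator builds complete worlds with known truth: a standardized
environmental stack (latitudinal gradient, an elevation-like ridge, and
Gaussian random fields with a set correlation range), an ultrametric
birth–death phylogeny (or a constructed one, below), Gaussian niches with
optima evolved by Brownian motion on the tree — a `phylo_signal` knob mixes
Brownian and independent optima convexly, since no niche-evolution model is
implied by the data being emulated — and occurrence samples drawn without
replacement with probability proportional to suitability × bias, jittered
uniformly within cells because real records are GPS points, not cell
indices. Per-species sample counts are log-uniform on [3, 42], matching the
sparse, skewed counts of the motivating survey (~10 per species). All
randomness descends from one integer seed through a documented splitting
scheme (one child stream per layer/species/stage), so worlds are
bit-reproducible.

Three presets encode the study designs the test-suite relies on:

* `southern_refuge` — 19 species in two replacing faunas: an old clade of
  six long-branch southern endemics (crown 85 Ma) plus five young southern
  species versus six young northern species, with two widespread species;
  the young radiation spans the last 12 Ma. The niche-defining climatic
  layer is the latitudinal gradient plus a sharp mid-latitude `tanh`
  discontinuity, emulating a biogeographic break across which seasonal
  climate changes abruptly; the faunas' range edges are therefore visible
  to the distribution models, which is what makes the truth recoverable in
  principle. Sampling is biased toward the west. A purely nested design
  (rich south containing the northern fauna) was rejected because
  turnover-only dissimilarity is blind to nestedness, making bioregion
  recovery ill-posed.
* `uniform` — every species suitable everywhere, unbiased sampling; the
  saturated true occupancy has identical richness in every cell. Null-model
  calibration uses the presence–absence matrix rasterized from the
  *sampled* occurrences, which is exchangeable across cells and therefore
  one more draw from the margin-fixed null — the saturated truth itself
  admits no randomization.
* `two_blocks` — disjoint northern and southern assemblages sharing no
  species; between-block Simpson dissimilarity is exactly 1.

What passing tests on these worlds show — and do not. They verify the index
algebra exactly, calibrate the null model, and demonstrate that the whole
chain (bias layer → tuning → thresholding → indices → clustering) recovers
gradients, refuge enrichment, and bioregions when the truth is driven by
the modelled environment. They do not show robustness to predictors missing
the true niche axes, to niche evolution more complex than Brownian, to
coastline/topography effects, or to the covariance structure of real
climate layers — none of which the generator attempts to mimic.

## Numerical and scale choices

Problem sizes in the tests were chosen as the smallest at which each
property is meaningful: 40 × 20 fine grids aggregated by 4 into 50 coarse
cells (≥ 50 cells keeps the uniformity test of null percentiles
informative), 99 null replicates in the end-to-end run and 999 for
calibration, a 10,000-point background (collapsed to distinct cells), and
leave-one-out evaluation for the many species with fewer than 20 points.
The optimizer runs to a relative objective tolerance of 1e-9 (at most
5000 iterations) so that 1-covariate fits agree with direct grid
maximization of the same objective to three decimals. Determinism is exact:
identical seeds give bit-identical CSV outputs.

Known limitations: no reprojection (all rasters must share one geographic
grid); no AICc-based model selection or threshold-free index variants; no
nestedness components of beta diversity; no neo/paleo-endemism
categorization; polygons are single outer rings. Where the motivating
study's procedure was ambiguous — fine- versus coarse-scale threshold
evaluation, cropping before or after thresholding, extent-wide versus
cropped range sizes, shared versus redrawn background — the default is
stated above and the alternative is exposed as a flag.
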