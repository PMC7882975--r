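---
title: "Ensemble SDMs, transferability and telemetry data efficiency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble SDMs, transferability and telemetry data efficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(sdmtransfer)
```

## The problem

Species distribution models (SDMs) built from telemetry usually face three
intertwined questions. First, multiple geographically distinct populations of
the same species may differ in their realized environment relationships, so a
model calibrated on one population may transfer poorly to another. Second,
modern GPS collars produce tens of thousands of locations per population,
most of them spatially redundant at the grain of the covariates, so it is
unclear how much data an SDM actually needs. Third, presence-only models need
evaluation statistics that respect the presence–background design rather than
assuming true absences.

`sdmtransfer` implements a complete, testable pipeline for these questions:
a presence–background ensemble model with an AUC-weighted combination rule at
its core, the occurrence-preparation steps around it, three
presence-background validation statistics, a PCA diagnostic of regional niche
variation, two orchestrated experiments (a 9-scenario transferability matrix
and 5–100% data-efficiency curves), and dual-threshold categorical habitat
mapping. Because real multi-population telemetry cannot be shipped, the
package includes a first-class virtual-species simulator whose ground truth
makes every stage verifiable.

## The ensemble model

The central fit is `fit_sdm_ensemble()`. For presences $P$ (deduplicated grid
cells) and a background extent $E$:

1. For each of $R$ background replicates, a fresh background of size $|P|$ is
   drawn by two-stage density sampling: a spatially uniform pool of
   $\lfloor \text{area}(E) \times d \rfloor$ distinct cells at density $d$
   (default 1 point per 1.5 km²), subsampled uniformly to $|P|$ cells.
   Presence cells are *not* excluded — this is a presence–background design.
2. Each registered algorithm is fitted to each replicate, giving
   $|A| \times R$ members (the reference configuration, 6 algorithms × 10
   replicates, yields 60). Every member exposes the same interface: a score
   function mapping covariate vectors to $[0,1]$, plus its training AUC.
3. Members are combined by the rule in `ensemble_weights()`: member $m$ is
   included iff $\mathrm{AUC}_m \ge \mathrm{median}(\mathrm{AUC}_{1..MR})$
   (even counts use the mean of the two middle values; ties at the median are
   included), and included members receive weights proportional to their raw
   AUC, normalized to sum to one. The ensemble score is the weighted average,
   a convex combination bounded by the member scores.

The registry (`sdm_algorithms()`) spans the learner families used in ensemble
SDM practice: logistic GLM; `mgcv` GAM; natural-spline logistic regression
(the flexible adaptive-spline family); random forest (`ranger`); boosted
trees (`xgboost`); and lasso-penalized logistic regression on linear plus
quadratic features, the standard glmnet-style approximation of Maxent for
presence–background data. Member AUC used for weighting is the training AUC
on the member's own presence/background draw; no inner holdout is performed
by default because the weighting rule, not honest member-level error, is the
quantity of interest. The returned `sdm_ensemble` object has `print`,
`summary`, `predict` (covariate rows or whole grids), `plot` and `weights`
methods, plus `permutation_importance()` for variable contributions
(1 − Pearson r between predictions before and after permuting a covariate).

## Evaluation statistics

* `auc_presence_background()` — rank AUC where the x-axis is the proportion
  of *background* scored at or above each threshold. The sweep-and-trapezoid
  implementation equals the Mann–Whitney pair statistic
  $P(s_P > s_B) + \tfrac12 P(s_P = s_B)$ exactly; the test suite asserts this
  identity against an independent pair-counting oracle on a thousand random
  instances, and agreement with `pROC` on untied data. Restricted integration
  bounds are available, but all reported statistics use the full $[0,1]$
  range, since single AUC numbers are what practitioners report.
* `boyce_index()` — continuous Boyce index: 101 moving windows of width 10%
  of the score range (both configurable, since conventions vary); within each
  window the predicted-to-expected ratio $P_i/E_i$ is computed from presence
  and area scores, empty windows are dropped, and the index is the Spearman
  correlation of $P_i/E_i$ against window position.
* `minimal_predicted_area()` — the largest threshold retaining a stated
  fraction (default 90%) of presence scores, using the lower-interpolation
  order statistic so the capture guarantee is exact, and the map area at or
  above it.

Evaluation backgrounds are drawn at 1 point per 10 km² over the evaluation
extent, and within an experiment each extent's background is drawn once and
shared across all models, so between-model AUC differences are never
background-sampling noise.

## Regional variation in environmental space

`run_pca()` ordinates presence cells on the (by default standardized)
covariates — standardization matches the default of the common PCA tools used
for this diagnostic, and a flag disables it. Component signs are fixed so
each loading column's largest-magnitude entry is positive, making results
stable across platforms. Per-population 95% ellipses use the normal-theory
$\chi^2_2$ radius. `niche_proximity()` reports centroid distance in the first
two components and a Jaccard ellipse-overlap fraction computed by indicator
integration on a 500 × 500 lattice over the joint bounding box — simple,
with bounded error (the suite verifies ~1e-5 accuracy against the closed-form
circle-intersection area). `proximity_transfer_diagnostic()` is the Spearman
correlation between proximity (negative centroid distance) and
cross-population AUC over ordered population pairs.

## The experiments

`build_default_scenarios()` enumerates each population crossed with two
background extents (own region vs whole region) plus region-level combined
models under three sample-size schemes: unequal (each population's own size)
and one "equal-to-reference" scheme per below-maximum population, capping
larger populations at the reference size while never inflating smaller ones.
With three populations this is exactly 9 scenarios.
`run_transfer_matrix()` fits one ensemble per scenario and evaluates it on
every population's withheld cells, the combined region, and the independent
sample. `run_efficiency()` subsamples one population's calibration cells at
5–100% (independent draws per fraction, not nested — matching how such
sensitivity analyses are described), refits the same ensemble per fraction
with an equal-sized background, and evaluates within-population, across
populations, and on independent data; `detect_plateau()` formalizes "where
the curve flattens" as the smallest fraction within ε (default 0.01 AUC) of
the curve maximum. Fractions are taken of the calibration pool with a fixed
withheld set, so evaluation data never leak into training at any fraction.

## Dual-threshold habitat mapping

`categorize()` converts a continuous map to high/moderate/low classes: the
high threshold captures 90% of calibration (GPS) presence scores, the
moderate threshold 85% of independent presence scores, both by the exact MPA
quantile rule; `bracket_maps()` produces the 95/90 and 85/80 bracketing
variants. Because independent data are broader in habitat use, their
threshold normally falls below the GPS threshold; if it does not, the
categories would invert, and the run aborts with a diagnostic rather than
silently swapping (swapping is available behind `allow_swap` and flagged),
since a swapped map means something different. `area_by_region()` tallies
exact per-region areas; the three classes partition the map by construction.

## What the simulator emulates — and what it does not

`simulate_study()` builds the full synthetic study:

* **Landscape** — stationary Gaussian random fields (white noise convolved
  with a Gaussian kernel, circularly, then restandardized), pairwise
  inter-covariate correlation induced by mixing with a shared field and
  capped at |0.7|, the usual collinearity screen. Default: 6 covariates,
  120 × 240 cells of 1 km², autocorrelation range 4 cells, r = 0.3.
* **Regions** — three equal rectangular blocks; real study areas are split
  along landscape features, but a labeled raster is the interface and
  rectangles are the default.
* **Niches** — Gaussian responses
  $\mathrm{logit}^{-1}\!\big(\mathrm{logit}(p_0) + \sum_j w_j e^{-(x_j-o_j)^2/2b_j^2} - \sum_j w_j/2\big)$.
  All populations share a core response (strong optimum on one covariate,
  weak on another); two further covariates carry graded optimum offsets that
  differentiate the populations. Three design points matter, each learned
  from explicit realized-niche diagnostics during development:
  the offsets are *symmetric* about the covariate mean (middle population at
  0, outer populations at ∓1.2), because one-sided ladders push the far
  population's optimum into covariate values the landscape barely contains,
  collapsing its realized niche back toward the core and scrambling the
  intended ordering; the two differentiation axes run *with* the positive
  inter-covariate correlation, for the same availability reason; and the
  differentiating weights (4 and 3, vs 5 for the core) are strong enough
  that far transfers genuinely degrade — with weak differentiation,
  cross-population AUCs compress into their own noise and no proximity
  signal exists to detect.
* **Telemetry** — collar centers drawn ∝ suitability within the population's
  region; fixes are Gaussian jitter (sd 4 cells) around the center, accepted
  with probability equal to destination suitability (rejection sampling), so
  presence intensity tracks suitability at two levels. Positional error is a
  90/10 mixture (≤100 vs 100–1000 distance units) so the ≤500 accuracy
  filter is exercisable. Fixes that cross a region border are clipped:
  populations are geographically disjoint by definition. Defaults give
  large/medium/small populations (≈2,500 / 900 / 350 cells before split)
  echoing the order-of-magnitude spread of real multi-population
  compilations without their absolute size; the efficiency experiment uses a
  scaled-up world (160 × 330 cells, 130 collars × 420 fixes) whose large
  population exceeds 5,000 presence cells.
* **Independent data** — 650 unclustered points drawn from the pooled
  suitability raised to the 0.5 power: a sparser sample with deliberately
  broader habitat use, mimicking compilations of sightings, genetic
  detections and camera traps.

Not emulated: real geodesy (only a cell size is carried), temporal structure
and fix-rate autocorrelation, prey dynamics, observation bias along roads,
and non-stationary covariate gradients between regions. Passing simulation
tests therefore demonstrate that the *pipeline* recovers structure a
generator of this class puts in; they do not certify performance on any real
landscape.

## Numerical and reproducibility choices

* One global integer seed; every stage derives a sub-stream via a stable
  polynomial string hash (`substream_seed()`), so any stage can be rerun in
  isolation bit-for-bit.
* Fractional counts use round-half-up (`round_half_up()`); this single rule
  reproduces all the published calibration/withheld size pairs the package's
  tests assert. Where a published selection (80% of 670 = 540) matches no
  standard rounding, explicit `target_n`/`calibration_n` overrides exist.
* Background pools are `floor(area × density)` distinct cells — a
  deterministic resolution of "approximately density d".
* The MPA/threshold quantile is the lower-interpolation order statistic, so
  capture guarantees are exact identities, not approximations.
* Degenerate inputs fail loudly: constant score surfaces (Boyce), empty
  extents, out-of-grid locations, unavailable covariates; constant
  *covariates* are dropped with warnings since that is routine in clipped
  training extents.

## Problem sizes used by the test suite

Simulation-backed checks run on deliberately desk-scale worlds: the
transferability and proximity properties use the default 120 × 240 world with
`glm` + spline members and 2 background replicates across 10 world seeds; the
efficiency property uses the 160 × 330 world at fractions {5%, 30%, 100%}
across 10 seeds. These members were chosen because the properties under test
concern sampling structure, not learner flexibility, and the two cheap
learners keep the full suite in the minutes range. The 60-member reference
configuration is exercised once on a small world to verify the accounting
and combination rule with all six algorithms.

## A worked example

```{r example, eval = FALSE}
world <- simulate_study(seed = 1)
tm <- run_transfer_matrix(world, algorithms = c("glm", "spline"),
                          n_replicates = 2, seed = 1)
print(tm)

curve <- run_efficiency(world, "central", fractions = seq(0.1, 1, 0.1),
                        algorithms = c("glm", "spline"), seed = 1)
detect_plateau(curve)

pca <- run_pca(do.call(rbind, world$calibration), world$stack)
niche_proximity(pca, "west", "east")
```

## Known limitations

* Maxent is approximated by penalized logistic regression; exact Maxent
  feature classes and the MARS algorithm itself are not implemented (a
  natural-spline GLM stands in for the adaptive-spline family).
* No hyperparameter search, spatial cross-validation blocking, or
  uncertainty maps — deliberately outside scope.
* Raster I/O is plain text (per-layer CSV plus a JSON sidecar); the package
  does not read or write GeoTIFF and carries no CRS.
* Member AUC for weighting is training AUC; with highly flexible members
  (random forest) this overweights them. The combination rule is the object
  of study, so this mirrors common practice, but an inner-holdout option
  would give more honest weights.
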