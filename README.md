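# sdmtransfer

Ensemble species distribution models (SDMs), cross-population
transferability, and telemetry data efficiency — with a virtual-species
simulator that makes every stage of the pipeline testable against known
ground truth.

## Who this is for

Spatial ecologists and biostatisticians who model habitat from telemetry
(GPS/Argos collars) under a presence–background design and need to answer:

* How well does a model calibrated on one population predict another, and
  does similarity of the populations in environmental (PCA) space anticipate
  that transferability?
* How much of a large GPS dataset does an SDM actually need before
  predictive performance plateaus?
* How should a continuous suitability surface be cut into defensible
  high/moderate/low habitat classes?

## The model

The core is an AUC-weighted presence–background ensemble. Presence cells
(telemetry deduplicated to the covariate grain) are contrasted against `R`
replicate background draws of equal size (two-stage density sampling, default
pool 1 point / 1.5 km²). Each of the registered algorithms — logistic GLM,
GAM, natural-spline GLM, random forest, boosted trees, and penalized
logistic regression as a Maxent-style learner — is fitted to every replicate
(reference configuration 6 × 10 = 60 members). Member `m` enters the
ensemble iff

    AUC_m >= median(AUC over all members)

and included members are averaged with weights proportional to their AUC
(normalized to sum to 1). Validation uses three presence-background
statistics, each implemented from its definition and tested against
independent oracles:

* **AUC** over the background-proportion axis (the rank statistic
  `P(s_P > s_B) + P(s_P = s_B)/2`),
* **continuous Boyce index** (Spearman correlation of predicted-to-expected
  presence ratios across moving score windows),
* **minimal predicted area** (exact capture-quantile threshold and the map
  area above it).

Around the core: occurrence preparation (accuracy filter, per-cell
deduplication, round-half-up fractional subsampling, calibration/withheld
splits), PCA niche diagnostics with per-population 95% ellipses, a
9-scenario transferability experiment, 5–100% data-efficiency curves with
plateau detection, and dual-threshold (90%/85%, with 95/90 and 85/80
brackets) categorical habitat maps with per-region area accounting.

## Worked example

```r
library(sdmtransfer)

world <- simulate_study(seed = 1)   # three-population virtual study
world
#> sdm_world (seed 1): 120 x 240 cells, populations: west, central, east
#>   west: calibration 238 / withheld 555 cells
#>   central: calibration 506 / withheld 1181 cells
#>   east: calibration 120 / withheld 279 cells
#>   independent: 635 cells

tm <- run_transfer_matrix(world, algorithms = c("glm", "spline"),
                          n_replicates = 2, seed = 1)
tm
#> transfer_matrix: 9 scenarios x 5 evaluation sets
#>            scenario_id  west central  east region independent
#>     west_bg_population 0.878   0.623 0.462  0.666       0.622
#>         west_bg_region 0.872   0.630 0.482  0.660       0.617
#>  central_bg_population 0.582   0.835 0.562  0.697       0.630
#>      central_bg_region 0.599   0.822 0.509  0.706       0.617
#>     east_bg_population 0.588   0.664 0.905  0.653       0.630
#>         east_bg_region 0.604   0.672 0.898  0.667       0.648
#>         region_unequal 0.746   0.794 0.669  0.749       0.671
#>   region_equal_to_west 0.785   0.771 0.705  0.747       0.676
#>   region_equal_to_east 0.762   0.758 0.766  0.740       0.678
```

Each row is one modeling scenario (training population or combined region ×
background extent × sample-size scheme), each column an evaluation set; the
cells are presence-background AUCs on withheld or independent data. The
pattern mirrors what multi-population telemetry studies report: every
single-population model is strongest at home (diagonal 0.84–0.91) and decays
with niche distance (the far `west`→`east` transfer drops to ~0.46), while
the combined-region models are the most even performers across all three
populations and the best on independent data.

```r
pca <- run_pca(do.call(rbind, world$calibration), world$stack)
pca
#> niche_pca: 864 presence cells, 6 components
#> variance explained (first two): 32.0%, 17.2%
#> populations: west, central, east

niche_proximity(pca, "west", "east")$centroid_distance
#> [1] 2.11   # the most differentiated pair, matching their worst transfer
```

`run_efficiency(world, "central", ...)` produces the sample-size curve and
`detect_plateau()` the smallest fraction within 0.01 AUC of its maximum;
`categorize(predict(ens, world$stack), ...)` converts the best model's
surface into the dual-threshold habitat map.

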