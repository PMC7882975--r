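#' Simulate a three-population virtual-species study
#'
#' Builds the full synthetic study on which the transferability and
#' data-efficiency experiments run: an autocorrelated covariate stack split
#' into disjoint rectangular population regions; one Gaussian niche per
#' population sharing a common core response but with graded optimum offsets
#' on a differentiating covariate (regional niche variation); GPS-like
#' clustered presence sampling per population at very different sample sizes;
#' an accuracy filter; per-cell deduplication; a calibration/withheld split;
#' and a sparser unclustered independent sample drawn with broadened habitat
#' use across the whole region.
#'
#' Defaults are deliberately desk-scale: three populations whose deduplicated
#' cell counts keep the large/medium/small structure of multi-population
#' telemetry compilations (one population an order of magnitude smaller than
#' the largest) without their absolute size.
#'
#' @param seed Integer global seed; every stage derives a sub-stream.
#' @param grid_dims Grid `c(nrow, ncol)`.
#' @param n_covariates Number of covariate layers.
#' @param autocorr_range_cells Spatial autocorrelation range of the layers.
#' @param inter_covariate_correlation Pairwise correlation between layers.
#' @param populations Region/population names (first = medium, second =
#'   large, third = small sample, mirroring the default collar numbers).
#' @param n_collars,fixes_per_collar Per-population telemetry intensity.
#' @param home_range_sd_cells Fix jitter sd (cells).
#' @param niche_offset Niche-optimum shift between successive populations on
#'   the two differentiating covariates (the middle population sits at the
#'   covariate mean, the outer two at minus/plus the offset); 0 makes all
#'   niches identical.
#' @param baseline_prevalence Niche baseline suitability.
#' @param calibration_fraction Calibration share of each population's cells.
#' @param n_independent Size of the independent validation sample.
#' @param independent_broadening Broadening exponent of the independent
#'   sample (< 1 flattens selectivity).
#' @param max_error Accuracy filter bound applied to raw locations.
#' @param cell_size_km Cell edge (km).
#' @return Object of class `sdm_world`: `stack`, `suitability` (per
#'   population), `calibration`/`withheld` (per population presence tables),
#'   `independent` (presence table), `niches`, `populations`, `seed`.
#' @export
simulate_study <- function(seed = 1L,
                           grid_dims = c(120L, 240L),
                           n_covariates = 6L,
                           autocorr_range_cells = 4,
                           inter_covariate_correlation = 0.3,
                           populations = c("west", "central", "east"),
                           n_collars = c(30L, 60L, 18L),
                           fixes_per_collar = c(70L, 140L, 35L),
                           home_range_sd_cells = 4,
                           niche_offset = 1.2,
                           baseline_prevalence = 0.05,
                           calibration_fraction = 0.3,
                           n_independent = 650L,
                           independent_broadening = 0.5,
                           max_error = 500,
                           cell_size_km = 1) {
  stopifnot(length(populations) >= 2L,
            length(n_collars) == length(populations),
            length(fixes_per_collar) == length(populations))
  region_labels <- default_region_partition(grid_dims, populations)
  stack <- generate_covariate_stack(
    n_covariates, grid_dims,
    autocorr_range_cells = autocorr_range_cells,
    inter_covariate_correlation = inter_covariate_correlation,
    seed = substream_seed(seed, "landscape"),
    cell_size_km = cell_size_km, region_labels = region_labels
  )
  covs <- names(stack$layers)
  niches <- list()
  suitability <- list()
  calibration <- list()
  withheld <- list()
  for (i in seq_along(populations)) {
    p <- populations[i]
    # shared niche core on cov1/cov3; graded offsets on cov2 and cov4
    # differentiate the populations' realized niches along two environmental
    # axes (regional variation is rarely one-dimensional). The offsets are
    # symmetric about the covariate mean (middle population at 0, the outer
    # two at -/+ offset) so every population's optimum is equally available
    # on the ground; the two gradients run together, with the landscape's
    # positive inter-covariate correlation, for the same reason.
    opt <- stats::setNames(
      c(1.2, (i - 2L) * niche_offset, -0.4, (i - 2L) * 0.8 * niche_offset),
      covs[1:4])
    niches[[p]] <- niche_spec(
      p, optimum = opt,
      breadth = stats::setNames(c(0.45, 0.5, 1, 0.5), covs[1:4]),
      weight = stats::setNames(c(5, 4, 1.5, 3), covs[1:4]),
      baseline_prevalence = baseline_prevalence
    )
    suitability[[p]] <- make_suitability(stack, niches[[p]])
    locs <- sample_gps_presences(
      suitability[[p]], stack, n_collars = n_collars[i],
      fixes_per_collar = fixes_per_collar[i],
      home_range_sd_cells = home_range_sd_cells,
      seed = substream_seed(seed, paste0("gps_", p))
    )
    locs <- filter_accuracy(locs, max_error)
    cells <- aggregate_to_cells(locs, stack)
    # populations are geographically disjoint by definition: fixes that
    # wander over a region boundary are clipped to the home region
    cells <- cells[region_labels[presence_cells(cells, stack)] == p, ,
                   drop = FALSE]
    sp <- split_calibration_withheld(
      cells, calibration_fraction,
      seed = substream_seed(seed, paste0("split_", p))
    )
    calibration[[p]] <- sp$calibration
    withheld[[p]] <- sp$withheld
  }
  # independent sample: broadened habitat use over the pooled suitability
  pooled <- structure(
    list(values = Reduce(`+`, lapply(suitability, `[[`, "values")) /
           length(suitability),
         population_id = "region"),
    class = "suitability_field"
  )
  ind_locs <- sample_independent_points(
    pooled, stack, n = n_independent, broadening = independent_broadening,
    seed = substream_seed(seed, "independent")
  )
  independent <- aggregate_to_cells(ind_locs, stack, split = "independent")
  structure(
    list(stack = stack, suitability = suitability, niches = niches,
         calibration = calibration, withheld = withheld,
         independent = independent, populations = populations, seed = seed),
    class = "sdm_world"
  )
}

#' @export
print.sdm_world <- function(x, ...) {
  cat("sdm_world (seed ", x$seed, "): ", paste(dim(x$stack), collapse = " x "),
      " cells, populations: ", paste(x$populations, collapse = ", "),
      "\n", sep = "")
  for (p in x$populations) {
    cat("  ", p, ": calibration ", nrow(x$calibration[[p]]),
        " / withheld ", nrow(x$withheld[[p]]), " cells\n", sep = "")
  }
  cat("  independent: ", nrow(x$independent), " cells\n", sep = "")
  invisible(x)
}

#' Enumerate the default modeling-scenario grid
#'
#' Crosses each population with the two background extents (its own region
#' vs the whole region), then adds the region-level (all populations
#' combined) sample-size schemes: `"unequal"` (each population's own size)
#' plus one `"equal_to_<p>"` scheme per population whose size is below the
#' maximum, capping every larger population at that reference size. With
#' three populations this enumerates exactly 9 scenarios.
#'
#' @param populations Population names (>= 2).
#' @param sizes Named per-population training sizes.
#' @return List of `scenario_spec` lists: `scenario_id`, `training_unit`
#'   (population name or `"region"`), `sample_size_scheme`,
#'   `background_extent`, `training_sizes` (named vector).
#' @export
build_default_scenarios <- function(populations, sizes) {
  stopifnot(length(populations) >= 2L)
  sizes <- sizes[populations]
  out <- list()
  for (p in populations) {
    for (ext in c(p, "region")) {
      out[[length(out) + 1L]] <- structure(
        list(scenario_id = paste0(p, "_bg_",
                                  if (ext == "region") "region" else "population"),
             training_unit = p, sample_size_scheme = "calibration",
             background_extent = ext,
             training_sizes = sizes[p]),
        class = "scenario_spec")
    }
  }
  schemes <- c("unequal",
               paste0("equal_to_", populations[sizes < max(sizes)]))
  for (sc in schemes) {
    tsz <- if (sc == "unequal") sizes else {
      ref <- sub("^equal_to_", "", sc)
      pmin(sizes, sizes[[ref]])
    }
    out[[length(out) + 1L]] <- structure(
      list(scenario_id = paste0("region_", sc), training_unit = "region",
           sample_size_scheme = sc, background_extent = "region",
           training_sizes = tsz),
      class = "scenario_spec")
  }
  out
}

# Assemble the training presence table a scenario prescribes.
scenario_training_table <- function(world, spec, seed) {
  if (spec$training_unit == "region") {
    parts <- lapply(world$populations, function(p) {
      tab <- world$calibration[[p]]
      subsample_fraction(tab, target_n = min(spec$training_sizes[[p]], nrow(tab)),
                         seed = substream_seed(seed, paste0("scheme_", spec$scenario_id, "_", p)))
    })
    do.call(rbind, parts)
  } else {
    world$calibration[[spec$training_unit]]
  }
}

#' Run the transferability scenario matrix
#'
#' Fits one ensemble per scenario and evaluates every fitted surface on each
#' population's withheld set, the combined-region withheld set, and the
#' independent set. Evaluation backgrounds (default 1 point per 10 km^2) are
#' drawn once per evaluation extent and shared across models, so AUC
#' differences between scenarios are not background-sampling noise.
#'
#' @param world An [simulate_study()] world.
#' @param scenarios List of scenario specs; default the 9-scenario grid over
#'   the world's calibration sizes.
#' @param algorithms Member algorithms (see [sdm_algorithms()]).
#' @param n_replicates Background replicates per algorithm.
#' @param seed Integer seed.
#' @param background_density Training background pool density (per km^2).
#' @param eval_background_density Evaluation background density (per km^2).
#' @return List of class `transfer_matrix`: `results` (long data.frame:
#'   scenario x evaluation set with `auc`, `boyce`, `mpa_*`), `ensembles`
#'   (per scenario), `scenarios`.
#' @export
run_transfer_matrix <- function(world,
                                scenarios = NULL,
                                algorithms = c("glm", "spline"),
                                n_replicates = 2L,
                                seed = 1L,
                                background_density = 1 / 1.5,
                                eval_background_density = 1 / 10) {
  if (is.null(scenarios)) {
    sizes <- vapply(world$calibration, nrow, 0L)[world$populations]
    scenarios <- build_default_scenarios(world$populations, sizes)
  }
  eval_sets <- c(stats::setNames(world$populations, world$populations),
                 region = "region")
  eval_bg <- lapply(eval_sets, function(ext) {
    sample_background(world$stack, ext,
                      initial_density_per_km2 = eval_background_density,
                      seed = substream_seed(seed, "eval_background"))
  })
  withheld_all <- do.call(rbind, world$withheld)
  rows <- list()
  ensembles <- list()
  for (spec in scenarios) {
    train <- scenario_training_table(world, spec, seed)
    ens <- fit_sdm_ensemble(
      train, world$stack, extent_tag = spec$background_extent,
      algorithms = algorithms, n_replicates = n_replicates,
      background_density = background_density,
      seed = substream_seed(seed, paste0("fit_", spec$scenario_id))
    )
    ensembles[[spec$scenario_id]] <- ens
    map <- predict(ens, world$stack)
    eval_tabs <- c(
      lapply(stats::setNames(world$populations, world$populations),
             function(p) list(tab = world$withheld[[p]], ext = p)),
      list(region = list(tab = withheld_all, ext = "region"),
           independent = list(tab = world$independent, ext = "region"))
    )
    for (es in names(eval_tabs)) {
      ext <- eval_tabs[[es]]$ext
      rep <- evaluate_predictions(
        map, world$stack, eval_tabs[[es]]$tab,
        background = eval_bg[[ext]]
      )
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(scenario_id = spec$scenario_id,
                   training_unit = spec$training_unit,
                   sample_size_scheme = spec$sample_size_scheme,
                   background_extent = spec$background_extent,
                   evaluation_set = es),
        rep
      )
    }
  }
  structure(
    list(results = do.call(rbind, rows), ensembles = ensembles,
         scenarios = scenarios, seed = seed),
    class = "transfer_matrix"
  )
}

#' @export
print.transfer_matrix <- function(x, ...) {
  cat("transfer_matrix: ", length(x$scenarios), " scenarios x ",
      length(unique(x$results$evaluation_set)), " evaluation sets\n", sep = "")
  wide <- stats::reshape(
    x$results[, c("scenario_id", "evaluation_set", "auc")],
    idvar = "scenario_id", timevar = "evaluation_set", direction = "wide"
  )
  names(wide) <- sub("^auc\\.", "", names(wide))
  print.data.frame(wide, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Data-efficiency curve for one population
#'
#' For each subsample fraction: draw an independent random subsample of the
#' population's calibration cells, draw an equal-sized background from the
#' population's extent, fit the same ensemble, and evaluate within the
#' population (withheld cells), on every other population, and on the
#' independent data. Fractions yielding fewer than 20 presences are skipped
#' with a warning.
#'
#' @param world An [simulate_study()] world.
#' @param population Population to subsample.
#' @param fractions Increasing fractions in (0, 1]; default 5% to 100% in 5%
#'   steps.
#' @param algorithms,n_replicates,background_density,seed As in
#'   [run_transfer_matrix()].
#' @param eval_background_density Evaluation background density.
#' @return data.frame of class `efficiency_curve`: one row per fraction with
#'   `n_train`, `auc_within`, one `auc_<pop>` per other population,
#'   `auc_independent`.
#' @export
run_efficiency <- function(world, population,
                           fractions = seq(0.05, 1, by = 0.05),
                           algorithms = c("glm", "spline"),
                           n_replicates = 2L,
                           background_density = 1 / 1.5,
                           eval_background_density = 1 / 10,
                           seed = 1L) {
  stopifnot(all(fractions > 0), all(fractions <= 1),
            population %in% world$populations)
  others <- setdiff(world$populations, population)
  eval_bg <- lapply(stats::setNames(c(population, others, "region"),
                                    c(population, others, "region")),
                    function(ext) {
                      sample_background(world$stack, ext,
                                        initial_density_per_km2 = eval_background_density,
                                        seed = substream_seed(seed, "eval_background"))
                    })
  cal <- world$calibration[[population]]
  rows <- list()
  for (f in fractions) {
    sub <- subsample_fraction(cal, f,
                              seed = substream_seed(seed, paste0("frac_", f)))
    if (nrow(sub) < 20L) {
      warning("fraction ", f, " yields ", nrow(sub),
              " presences (< 20); skipped", call. = FALSE)
      next
    }
    ens <- fit_sdm_ensemble(
      sub, world$stack, extent_tag = population,
      algorithms = algorithms, n_replicates = n_replicates,
      background_density = background_density,
      seed = substream_seed(seed, paste0("fit_frac_", f))
    )
    map <- predict(ens, world$stack)
    row <- data.frame(fraction = f, n_train = nrow(sub))
    row$auc_within <- evaluate_predictions(
      map, world$stack, world$withheld[[population]],
      background = eval_bg[[population]])$auc
    for (p in others) {
      row[[paste0("auc_", p)]] <- evaluate_predictions(
        map, world$stack, world$withheld[[p]], background = eval_bg[[p]])$auc
    }
    row$auc_independent <- evaluate_predictions(
      map, world$stack, world$independent, background = eval_bg$region)$auc
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  attr(out, "population") <- population
  class(out) <- c("efficiency_curve", "data.frame")
  out
}

#' @export
plot.efficiency_curve <- function(x, ...) {
  auc_cols <- grep("^auc_", names(x), value = TRUE)
  cols <- grDevices::palette.colors(length(auc_cols))
  graphics::matplot(x$fraction, as.matrix(x[, auc_cols]), type = "b",
                    pch = 16, lty = 1, col = cols,
                    xlab = "subsample fraction", ylab = "AUC", ...)
  graphics::legend("bottomright", legend = sub("^auc_", "", auc_cols),
                   col = cols, lty = 1, pch = 16, bty = "n")
  invisible(x)
}

#' Detect the data-efficiency plateau of an AUC curve
#'
#' The smallest fraction whose within-population AUC is within `epsilon` of
#' the curve's maximum — a formal stand-in for eyeballing where the curve
#' flattens.
#'
#' @param curve An `efficiency_curve` (or data.frame with `fraction` and
#'   `auc_within`).
#' @param epsilon AUC tolerance (default 0.01).
#' @return The plateau fraction.
#' @export
detect_plateau <- function(curve, epsilon = 0.01) {
  stopifnot(nrow(curve) >= 3L)
  ok <- curve$auc_within >= max(curve$auc_within) - epsilon
  curve$fraction[which(ok)[1L]]
}
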