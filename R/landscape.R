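#' Construct a covariate grid stack
#'
#' A `grid_stack` is the package's in-memory landscape: a named list of
#' numeric matrices (one per covariate, identical dimensions), a cell size in
#' km, and a character matrix of region labels (`"none"` for cells outside any
#' region). It stands in for an aligned multi-band raster.
#'
#' @param layers Named list of numeric matrices with identical dimensions.
#' @param cell_size_km Positive cell edge length in km.
#' @param region_labels Character matrix of the same dimensions, or `NULL` for
#'   a single region `"region"` covering every cell.
#' @return An object of class `grid_stack`.
#' @export
grid_stack <- function(layers, cell_size_km = 1, region_labels = NULL) {
  stopifnot(is.list(layers), length(layers) >= 1L)
  if (is.null(names(layers)) || anyNA(names(layers)) || any(names(layers) == ""))
    stop("covariate layers must be named")
  dims <- dim(layers[[1L]])
  for (nm in names(layers)) {
    if (!is.matrix(layers[[nm]]) || !identical(dim(layers[[nm]]), dims))
      stop("layer '", nm, "' does not match the shared grid dimensions")
  }
  if (!is.numeric(cell_size_km) || length(cell_size_km) != 1L || cell_size_km <= 0)
    stop("cell_size_km must be a positive scalar")
  if (is.null(region_labels)) {
    region_labels <- matrix("region", dims[1L], dims[2L])
  }
  stopifnot(identical(dim(region_labels), dims))
  structure(
    list(layers = layers, cell_size_km = cell_size_km,
         region_labels = region_labels),
    class = "grid_stack"
  )
}

#' @export
print.grid_stack <- function(x, ...) {
  d <- dim(x$layers[[1L]])
  cat("grid_stack: ", d[1L], " x ", d[2L], " cells (",
      format(x$cell_size_km), " km), ", length(x$layers),
      " covariates: ", paste(names(x$layers), collapse = ", "), "\n", sep = "")
  regs <- setdiff(unique(as.vector(x$region_labels)), "none")
  cat("regions: ", paste(regs, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.grid_stack <- function(x) dim(x$layers[[1L]])

#' Cell area of a grid stack in square km
#' @param stack A `grid_stack`.
#' @return Scalar area of one cell (km^2).
#' @export
cell_area_km2 <- function(stack) stack$cell_size_km^2

#' Linear cell indices belonging to an extent
#'
#' `extent_tag` is either a region label present in `region_labels` or the
#' special tag `"region"`, meaning every cell with a label other than `"none"`.
#'
#' @param stack A `grid_stack`.
#' @param extent_tag Character region label or `"region"`.
#' @return Integer vector of linear (column-major) cell indices.
#' @export
extent_cells <- function(stack, extent_tag = "region") {
  lab <- stack$region_labels
  idx <- if (identical(extent_tag, "region")) {
    which(lab != "none")
  } else {
    which(lab == extent_tag)
  }
  if (length(idx) == 0L)
    stop("extent '", extent_tag, "' contains no cells")
  idx
}

#' Covariate matrix at a set of cells
#'
#' @param stack A `grid_stack`.
#' @param cells Integer vector of linear cell indices.
#' @return Numeric matrix, one row per cell, one column per covariate.
#' @export
covariates_at <- function(stack, cells) {
  out <- vapply(stack$layers, function(m) m[cells], numeric(length(cells)))
  if (length(cells) == 1L) out <- matrix(out, nrow = 1L,
                                         dimnames = list(NULL, names(stack$layers)))
  colnames(out) <- names(stack$layers)
  out
}

# Circular (wrap-around) Gaussian smoothing of a matrix via 2-D FFT
# convolution; wrap-around keeps the smoothed field stationary (no edge
# attenuation), which the restandardization step relies on.
smooth_field <- function(m, range_cells) {
  if (range_cells <= 0) return(m)
  gauss_1d <- function(n, s) {
    d <- pmin(0:(n - 1L), n - (0:(n - 1L))) # circular distance to origin
    k <- exp(-d^2 / (2 * s^2))
    k / sum(k)
  }
  k2 <- outer(gauss_1d(nrow(m), range_cells), gauss_1d(ncol(m), range_cells))
  Re(stats::fft(stats::fft(m) * stats::fft(k2), inverse = TRUE)) / length(m)
}

#' Generate a stack of standardized autocorrelated covariate fields
#'
#' Each layer is a stationary Gaussian random field built by circular
#' convolution of white noise with a Gaussian kernel of the requested range,
#' then restandardized to mean 0 and variance 1. Pairwise correlation between
#' layers is induced by mixing each independent field with one shared field;
#' correlations are capped at |0.7|, mirroring the collinearity screen commonly
#' applied to SDM covariate sets.
#'
#' @param n_covariates Number of layers (>= 2).
#' @param grid_dims Integer vector `c(nrow, ncol)`, each >= 16.
#' @param autocorr_range_cells Gaussian kernel sd in cells (0 = white noise).
#' @param inter_covariate_correlation Target pairwise Pearson correlation,
#'   `|r| <= 0.7`. Negative values are only meaningful for 2 layers.
#' @param seed Integer seed; identical seeds give bit-identical stacks.
#' @param cell_size_km Cell edge length in km.
#' @param region_labels Optional region-label matrix (see [grid_stack()]).
#' @return A [grid_stack()] with layers `cov1 ... covK`.
#' @export
generate_covariate_stack <- function(n_covariates, grid_dims,
                                     autocorr_range_cells = 0,
                                     inter_covariate_correlation = 0,
                                     seed = 1L,
                                     cell_size_km = 1,
                                     region_labels = NULL) {
  stopifnot(n_covariates >= 2L, length(grid_dims) == 2L, all(grid_dims >= 16L),
            autocorr_range_cells >= 0)
  rho <- inter_covariate_correlation
  if (abs(rho) > 0.7)
    stop("inter-covariate correlation above the |0.7| screening bound; ",
         "covariate sets are screened to pairwise r <= |0.7|")
  if (rho < 0 && n_covariates > 2L)
    stop("negative equicorrelation is only supported for 2 covariates")
  set.seed(substream_seed(seed, "covariate_stack"))
  nr <- as.integer(grid_dims[1L]); nc <- as.integer(grid_dims[2L])
  field <- function() {
    f <- smooth_field(matrix(stats::rnorm(nr * nc), nr, nc),
                      autocorr_range_cells)
    (f - mean(f)) / stats::sd(f)
  }
  shared <- field()
  layers <- vector("list", n_covariates)
  for (j in seq_len(n_covariates)) {
    e <- field()
    f <- if (rho >= 0) {
      sqrt(rho) * shared + sqrt(1 - rho) * e
    } else if (j == 1L) {
      shared
    } else {
      rho * shared + sqrt(1 - rho^2) * e
    }
    layers[[j]] <- (f - mean(f)) / stats::sd(f)
  }
  names(layers) <- paste0("cov", seq_len(n_covariates))
  grid_stack(layers, cell_size_km = cell_size_km, region_labels = region_labels)
}

#' Default region partition: side-by-side rectangular blocks
#'
#' Splits the grid into `length(region_names)` vertical blocks of (near) equal
#' width, one per region. Real study areas are partitioned along landscape
#' features; rectangles are the simulator's default stand-in.
#'
#' @param grid_dims `c(nrow, ncol)`.
#' @param region_names Character vector of region labels.
#' @return Character matrix of labels.
#' @export
default_region_partition <- function(grid_dims, region_names) {
  nr <- grid_dims[1L]; nc <- grid_dims[2L]
  k <- length(region_names)
  breaks <- round(seq(0, nc, length.out = k + 1L))
  lab <- matrix("none", nr, nc)
  for (i in seq_len(k)) {
    lab[, (breaks[i] + 1L):breaks[i + 1L]] <- region_names[i]
  }
  lab
}

#' Specify a Gaussian niche response
#'
#' Encodes one population's environmental niche: a Gaussian response per
#' covariate with an optimum, a breadth (response sd) and a weight, plus a
#' baseline prevalence controlling overall suitability level. Regional niche
#' differentiation between populations is expressed by shifting optima.
#'
#' @param population_id Character id.
#' @param optimum,breadth,weight Named numeric vectors over (a subset of) the
#'   stack covariates. Breadths must be positive, weights non-negative with at
#'   least one positive (unless all weights are zero for a flat niche).
#' @param baseline_prevalence Baseline suitability in (0, 1).
#' @return An object of class `niche_spec`.
#' @export
niche_spec <- function(population_id, optimum, breadth, weight,
                       baseline_prevalence = 0.5) {
  stopifnot(length(optimum) == length(breadth),
            length(optimum) == length(weight),
            all(breadth > 0), all(weight >= 0),
            baseline_prevalence > 0, baseline_prevalence < 1)
  nm <- names(optimum)
  if (is.null(nm)) stop("optimum must be named by covariate")
  structure(
    list(population_id = population_id,
         optimum = stats::setNames(as.numeric(optimum), nm),
         breadth = stats::setNames(as.numeric(breadth), nm),
         weight = stats::setNames(as.numeric(weight), nm),
         baseline_prevalence = baseline_prevalence),
    class = "niche_spec"
  )
}

#' Ground-truth suitability from a niche specification
#'
#' Computes the virtual species' suitability on every cell:
#' `logistic( logit(p0) + sum_j w_j exp(-(x_j - o_j)^2 / (2 b_j^2)) - sum_j w_j / 2 )`,
#' a Gaussian-response virtual species whose suitability peaks exactly at the
#' niche optimum and decays monotonically with distance from it in each
#' covariate.
#'
#' @param stack A [grid_stack()].
#' @param niche A [niche_spec()]; its covariates must exist in the stack.
#' @return An object of class `suitability_field`: list of `values` (matrix in
#'   (0,1)) and `population_id`.
#' @export
make_suitability <- function(stack, niche) {
  nm <- names(niche$optimum)
  missing_cov <- setdiff(nm, names(stack$layers))
  if (length(missing_cov))
    stop("niche covariate(s) not in stack: ", paste(missing_cov, collapse = ", "))
  d <- dim(stack)
  lin <- matrix(stats::qlogis(niche$baseline_prevalence), d[1L], d[2L])
  for (j in nm) {
    w <- niche$weight[[j]]
    if (w == 0) next
    x <- stack$layers[[j]]
    lin <- lin + w * exp(-(x - niche$optimum[[j]])^2 /
                           (2 * niche$breadth[[j]]^2)) - w / 2
  }
  structure(
    list(values = plogis_(lin), population_id = niche$population_id),
    class = "suitability_field"
  )
}

#' @export
print.suitability_field <- function(x, ...) {
  cat("suitability_field for population '", x$population_id, "': ",
      nrow(x$values), " x ", ncol(x$values), " cells, range [",
      format(min(x$values), digits = 3), ", ",
      format(max(x$values), digits = 3), "]\n", sep = "")
  invisible(x)
}

# Draw positional errors from the default accuracy mixture: 90% of fixes with
# error in (0, 100], 10% in (100, 1000] (same length unit as the covariates'
# native resolution, i.e. meters for a 250 m grid).
draw_positional_error <- function(n) {
  coarse <- stats::runif(n) < 0.1
  ifelse(coarse, stats::runif(n, 100, 1000), stats::runif(n, 0, 100))
}

#' Simulate GPS-collar presence locations over a suitability field
#'
#' Emulates telemetry sampling: few individuals, each contributing many
#' spatially clustered fixes. Collar centers are drawn from the population's
#' region with probability proportional to suitability; each fix is the center
#' plus isotropic Gaussian jitter (`home_range_sd_cells`), accepted with
#' probability equal to the destination cell's suitability (rejection
#' sampling), so fix density tracks suitability within the home range.
#' Each fix carries a positional error drawn from a mixture (90% of fixes
#' with error at most 100, 10% in (100, 1000]) so downstream accuracy
#' filtering is exercisable.
#'
#' @param field A `suitability_field`.
#' @param stack The [grid_stack()] the field was computed on.
#' @param n_collars Number of individuals (>= 1).
#' @param fixes_per_collar Accepted fixes per individual (>= 1).
#' @param home_range_sd_cells Gaussian jitter sd, in cells; 0 pins every fix
#'   to its collar's center cell.
#' @param seed Integer seed.
#' @param region Region label restricting collar placement; defaults to the
#'   field's population id.
#' @return data.frame with columns `x`, `y` (continuous, cell units),
#'   `collar_id`, `population`, `error`, `source = "gps"`.
#' @export
sample_gps_presences <- function(field, stack, n_collars, fixes_per_collar,
                                 home_range_sd_cells = 3, seed = 1L,
                                 region = field$population_id) {
  stopifnot(n_collars >= 1L, fixes_per_collar >= 1L, home_range_sd_cells >= 0)
  set.seed(substream_seed(seed, paste0("gps_", field$population_id)))
  d <- dim(stack)
  cells <- extent_cells(stack, region)
  w <- field$values[cells]
  if (sum(w) <= 0) stop("region '", region, "' has zero total suitability")
  centers <- cells[sample.int(length(cells), n_collars, replace = TRUE,
                              prob = w)]
  crow <- (centers - 1L) %% d[1L] + 1L
  ccol <- (centers - 1L) %/% d[1L] + 1L
  out <- vector("list", n_collars)
  for (i in seq_len(n_collars)) {
    cx <- ccol[i] - 0.5; cy <- crow[i] - 0.5
    acc_x <- numeric(0); acc_y <- numeric(0)
    while (length(acc_x) < fixes_per_collar) {
      m <- max(2L * (fixes_per_collar - length(acc_x)), 16L)
      px <- cx + stats::rnorm(m, 0, home_range_sd_cells)
      py <- cy + stats::rnorm(m, 0, home_range_sd_cells)
      col <- ceiling(px); row <- ceiling(py)
      inside <- col >= 1L & col <= d[2L] & row >= 1L & row <= d[1L]
      p <- numeric(m)
      p[inside] <- field$values[cbind(row[inside], col[inside])]
      keep <- stats::runif(m) < p
      acc_x <- c(acc_x, px[keep]); acc_y <- c(acc_y, py[keep])
    }
    out[[i]] <- data.frame(
      x = acc_x[seq_len(fixes_per_collar)],
      y = acc_y[seq_len(fixes_per_collar)],
      collar_id = paste0(field$population_id, "_c", i)
    )
  }
  res <- do.call(rbind, out)
  res$population <- field$population_id
  res$error <- draw_positional_error(nrow(res))
  res$source <- "gps"
  rownames(res) <- NULL
  res
}

#' Simulate an unclustered independent validation sample
#'
#' Draws `n` single locations (no collar structure) with per-cell probability
#' proportional to `suitability^broadening`. A broadening exponent below 1
#' flattens selectivity, mimicking independent datasets (sightings, genetic
#' detections, camera traps) that span a wider array of behaviors and hence of
#' habitat use than resident GPS-collared animals.
#'
#' @param field A `suitability_field`.
#' @param stack The [grid_stack()].
#' @param n Number of locations.
#' @param broadening Exponent in (0, 1]; 1 reproduces suitability-proportional
#'   sampling.
#' @param seed Integer seed.
#' @param region Region label to draw from; `"region"` for the whole labeled
#'   area.
#' @return data.frame like [sample_gps_presences()] with `source =
#'   "independent"` and `collar_id = NA`.
#' @export
sample_independent_points <- function(field, stack, n, broadening = 1,
                                      seed = 1L, region = "region") {
  stopifnot(n >= 1L, broadening > 0, broadening <= 1)
  set.seed(substream_seed(seed, paste0("independent_", region)))
  d <- dim(stack)
  cells <- extent_cells(stack, region)
  w <- field$values[cells]^broadening
  if (sum(w) <= 0) stop("empty suitability over region '", region, "'")
  pick <- cells[sample.int(length(cells), n, replace = TRUE, prob = w)]
  row <- (pick - 1L) %% d[1L] + 1L
  col <- (pick - 1L) %/% d[1L] + 1L
  data.frame(
    x = col - stats::runif(n), y = row - stats::runif(n),
    collar_id = NA_character_,
    population = field$population_id,
    error = 0,
    source = "independent"
  )
}
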