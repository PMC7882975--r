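#' Filter locations by positional accuracy
#'
#' Keeps locations whose positional error is at most `max_error` (inclusive),
#' the usual screen applied to Argos-class telemetry before it is mixed with
#' GPS fixes.
#'
#' @param locations data.frame with an `error` column (non-negative).
#' @param max_error Inclusive error bound, same units as `error`.
#' @return The retained rows of `locations`.
#' @export
filter_accuracy <- function(locations, max_error) {
  if (!"error" %in% names(locations))
    stop("locations have no 'error' column")
  if (any(locations$error < 0, na.rm = TRUE))
    stop("negative positional errors")
  locations[locations$error <= max_error, , drop = FALSE]
}

#' Collapse raw locations to one presence observation per grid cell
#'
#' Telemetry is far denser than the covariate grain; all locations falling in
#' one cell become a single presence observation. Rows are grouped by
#' (population, cell) and returned in row-major cell order; `n_source` counts
#' the collapsed locations.
#'
#' @param locations data.frame with continuous `x`, `y` in cell units
#'   (cell `(r, c)` covers `x` in `(c-1, c]`, `y` in `(r-1, r]`) and a
#'   `population` column.
#' @param stack A [grid_stack()] defining the grid.
#' @param split Split tag recorded on every row (default `"unsplit"`; use
#'   [split_calibration_withheld()] to assign calibration/withheld).
#' @return A presence table: data.frame with columns `row`, `col`,
#'   `population`, `split`, `n_source`.
#' @export
aggregate_to_cells <- function(locations, stack, split = "unsplit") {
  d <- dim(stack)
  col <- ceiling(locations$x)
  row <- ceiling(locations$y)
  bad <- which(col < 1L | col > d[2L] | row < 1L | row > d[1L] |
                 !is.finite(col) | !is.finite(row))
  if (length(bad))
    stop("locations outside the grid at rows: ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) ", ...")
  pop <- if ("population" %in% names(locations)) locations$population else "all"
  key <- paste(pop, row, col, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(
    row = as.integer(vapply(parts, `[`, "", 2L)),
    col = as.integer(vapply(parts, `[`, "", 3L)),
    population = vapply(parts, `[`, "", 1L),
    split = split,
    n_source = as.integer(tab)
  )
  out <- out[order(out$population, out$row, out$col), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Random fractional subsample of a presence table
#'
#' Retains `round_half_up(fraction * n)` rows, drawn uniformly without
#' replacement. Subsamples at different fractions are independent draws, not
#' nested. The deterministic count rule reproduces printed study sizes, e.g.
#' 30% of 22,510 cells is 6,753 and 5% of 670 is 34.
#'
#' @param table Presence table (any data.frame; rows are the sampling units).
#' @param fraction In (0, 1].
#' @param seed Integer seed.
#' @param target_n Optional explicit count overriding the fraction rule (used
#'   when a study fixes a count, e.g. 540, that no standard rounding of a
#'   fraction reproduces).
#' @return The retained rows.
#' @export
subsample_fraction <- function(table, fraction = NULL, seed = 1L,
                               target_n = NULL) {
  n <- nrow(table)
  if (is.null(target_n)) {
    if (is.null(fraction) || fraction <= 0 || fraction > 1)
      stop("fraction must be in (0, 1]")
    k <- round_half_up(fraction * n)
  } else {
    stopifnot(target_n >= 0L, target_n <= n)
    k <- as.integer(target_n)
  }
  if (k == n) return(table)
  set.seed(substream_seed(seed, "subsample"))
  out <- table[sort(sample.int(n, k)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split a presence table into calibration and withheld sets
#'
#' Disjoint, exhaustive partition; the calibration size follows the same
#' round-half-up rule as [subsample_fraction()] (30% of 7,476 gives
#' calibration 2,243 and withheld 5,233), or an explicit `calibration_n`.
#'
#' @param table Presence table.
#' @param calibration_fraction In (0, 1).
#' @param seed Integer seed.
#' @param calibration_n Optional explicit calibration count.
#' @return List with elements `calibration` and `withheld`, each a presence
#'   table with its `split` column set.
#' @export
split_calibration_withheld <- function(table, calibration_fraction = NULL,
                                       seed = 1L, calibration_n = NULL) {
  n <- nrow(table)
  if (is.null(calibration_n)) {
    if (is.null(calibration_fraction) || calibration_fraction <= 0 ||
        calibration_fraction >= 1)
      stop("calibration_fraction must be in (0, 1)")
    k <- round_half_up(calibration_fraction * n)
  } else {
    stopifnot(calibration_n > 0L, calibration_n < n)
    k <- as.integer(calibration_n)
  }
  set.seed(substream_seed(seed, "split"))
  idx <- sort(sample.int(n, k))
  cal <- table[idx, , drop = FALSE]
  wh <- table[-idx, , drop = FALSE]
  if ("split" %in% names(table)) {
    cal$split <- "calibration"
    wh$split <- "withheld"
  }
  rownames(cal) <- rownames(wh) <- NULL
  list(calibration = cal, withheld = wh)
}

#' Two-stage density-based background sample
#'
#' Stage one draws a spatially uniform pool of `floor(extent_area * density)`
#' distinct cells over the extent; stage two subsamples the pool uniformly to
#' exactly `target_n` cells. Presence cells are not excluded: this is a
#' presence-background design, not presence-absence.
#'
#' @param stack A [grid_stack()].
#' @param extent_tag Region label or `"region"` (see [extent_cells()]).
#' @param initial_density_per_km2 Pool density, points per km^2 (e.g. `1/1.5`).
#' @param target_n Final sample size; must not exceed the pool.
#' @param seed Integer seed.
#' @return List of class `background_sample`: `cells` (integer linear indices),
#'   `extent_tag`, `pool_n`, `density_per_km2`.
#' @export
sample_background <- function(stack, extent_tag, initial_density_per_km2,
                              target_n = NULL, seed = 1L) {
  cells <- extent_cells(stack, extent_tag)
  area <- length(cells) * cell_area_km2(stack)
  pool_n <- floor(area * initial_density_per_km2)
  if (pool_n < 1L) stop("density too low: empty background pool")
  if (pool_n > length(cells))
    stop("background pool (", pool_n, ") exceeds the ", length(cells),
         " cells in extent '", extent_tag, "'; lower the density")
  if (is.null(target_n)) target_n <- pool_n
  if (target_n > pool_n)
    stop("target_n (", target_n, ") exceeds the background pool (", pool_n,
         "); raise initial_density_per_km2")
  set.seed(substream_seed(seed, paste0("background_", extent_tag)))
  pool <- cells[sample.int(length(cells), pool_n)]
  keep <- if (target_n == pool_n) pool else pool[sample.int(pool_n, target_n)]
  structure(
    list(cells = keep, extent_tag = extent_tag, pool_n = pool_n,
         density_per_km2 = initial_density_per_km2),
    class = "background_sample"
  )
}

#' Linear cell indices of a presence table on a stack
#' @param table Presence table with `row`, `col`.
#' @param stack A [grid_stack()].
#' @return Integer vector of linear indices.
#' @export
presence_cells <- function(table, stack) {
  d <- dim(stack)
  (table$col - 1L) * d[1L] + table$row
}
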