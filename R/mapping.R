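#' Dual-threshold categorical habitat map
#'
#' Converts a continuous suitability map into high / moderate / low classes.
#' The high threshold is the capture-quantile threshold
#' ([mpa_threshold()]) that keeps `high_capture` of the calibration presence
#' scores at or above it; the moderate threshold likewise keeps
#' `moderate_capture` of the independent presence scores. A cell scoring at
#' or above the high threshold is `high`; below it but at or above the
#' moderate threshold is `moderate`; the residual class is `low`.
#'
#' Because independent data typically span broader habitat use, their
#' threshold normally falls below the calibration threshold. If it does not,
#' categories would invert, and the run aborts with a diagnostic unless
#' `allow_swap = TRUE`, in which case the thresholds are swapped and the
#' result flagged.
#'
#' @param map A `suitability_map`.
#' @param stack The [grid_stack()] (for presence scoring and region areas).
#' @param calibration_presences,independent_presences Presence tables.
#' @param high_capture,moderate_capture Capture levels in (0, 1], defaults
#'   0.90 and 0.85.
#' @param allow_swap Swap inverted thresholds instead of aborting.
#' @return Object of class `habitat_map`: `category` (character matrix),
#'   `t_high`, `t_moderate`, `captures`, `swapped`, `area_km2` (per-region x
#'   category table from [area_by_region()]).
#' @export
categorize <- function(map, stack, calibration_presences,
                       independent_presences,
                       high_capture = 0.90, moderate_capture = 0.85,
                       allow_swap = FALSE) {
  stopifnot(high_capture > 0, high_capture <= 1,
            moderate_capture > 0, moderate_capture <= 1)
  s_cal <- map$values[presence_cells(calibration_presences, stack)]
  s_ind <- map$values[presence_cells(independent_presences, stack)]
  t_high <- mpa_threshold(s_cal, high_capture)
  t_mod <- mpa_threshold(s_ind, moderate_capture)
  swapped <- FALSE
  if (t_mod > t_high) {
    if (!allow_swap)
      stop("independent-data threshold (", format(t_mod, digits = 4),
           ") exceeds the calibration threshold (",
           format(t_high, digits = 4), "): categories would invert. ",
           "Inspect the presence sets, or set allow_swap = TRUE to swap ",
           "thresholds (flagged in the result).")
    tmp <- t_high; t_high <- t_mod; t_mod <- tmp
    swapped <- TRUE
  }
  cat_m <- matrix("low", nrow(map$values), ncol(map$values))
  cat_m[map$values >= t_mod] <- "moderate"
  cat_m[map$values >= t_high] <- "high"
  out <- structure(
    list(category = cat_m, t_high = t_high, t_moderate = t_mod,
         captures = c(high = high_capture, moderate = moderate_capture),
         swapped = swapped, cell_area_km2 = map$cell_area_km2),
    class = "habitat_map"
  )
  out$area_km2 <- area_by_region(out, stack$region_labels)
  out
}

#' @export
print.habitat_map <- function(x, ...) {
  cat("habitat_map: thresholds high >= ", format(x$t_high, digits = 4),
      ", moderate >= ", format(x$t_moderate, digits = 4),
      if (x$swapped) " (thresholds swapped)", "\n", sep = "")
  print(x$area_km2, digits = 6)
  invisible(x)
}

#' @export
plot.habitat_map <- function(x, ...) {
  z <- matrix(match(x$category, c("low", "moderate", "high")),
              nrow(x$category), ncol(x$category))
  graphics::image(t(z)[, rev(seq_len(nrow(z)))], useRaster = TRUE,
                  axes = FALSE, col = c("grey90", "goldenrod", "forestgreen"),
                  ...)
  graphics::legend("topright", fill = c("forestgreen", "goldenrod", "grey90"),
                   legend = c("high", "moderate", "low"), bty = "n")
  invisible(x)
}

#' Habitat area by region and category
#'
#' Cell counts per (region, category) scaled by cell area, with a totals row
#' equal to the whole-map tally. Areas over the three categories partition
#' each region exactly.
#'
#' @param cat_map A `habitat_map`, or a character category matrix (then
#'   `cell_area` is required).
#' @param region_labels Region-label matrix aligned to the map.
#' @param cell_area Cell area in km^2 for a bare matrix.
#' @return data.frame: `region`, `high`, `moderate`, `low`, `total` (km^2),
#'   with a final `"total"` row.
#' @export
area_by_region <- function(cat_map, region_labels, cell_area = NULL) {
  if (inherits(cat_map, "habitat_map")) {
    m <- cat_map$category
    cell_area <- cat_map$cell_area_km2
  } else {
    m <- cat_map
    if (is.null(cell_area)) stop("cell_area required for a bare matrix")
  }
  if (!identical(dim(m), dim(region_labels)))
    stop("region raster is not aligned to the categorical map")
  regs <- sort(setdiff(unique(as.vector(region_labels)), character(0)))
  cats <- c("high", "moderate", "low")
  rows <- lapply(c(regs, "total"), function(r) {
    sel <- if (r == "total") rep(TRUE, length(m)) else region_labels == r
    counts <- vapply(cats, function(cc) sum(m[sel] == cc), 0)
    data.frame(region = r, high = counts[1L] * cell_area,
               moderate = counts[2L] * cell_area,
               low = counts[3L] * cell_area,
               total = sum(counts) * cell_area)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Categorical maps under a set of bracketing capture pairs
#'
#' Produces one [categorize()] map per `(high_capture, moderate_capture)`
#' pair, e.g. the default brackets around a 90/85 rule. High-category area
#' is monotone non-decreasing in the high capture level.
#'
#' @param map A `suitability_map`.
#' @param stack The [grid_stack()].
#' @param calibration_presences,independent_presences Presence tables.
#' @param brackets List of `c(high, moderate)` pairs; default
#'   `(0.95, 0.90), (0.90, 0.85), (0.85, 0.80)`.
#' @param allow_swap Passed to [categorize()].
#' @return Named list of `habitat_map`s (`"h0.9_m0.85"` etc.).
#' @export
bracket_maps <- function(map, stack, calibration_presences,
                         independent_presences,
                         brackets = list(c(0.95, 0.90), c(0.90, 0.85),
                                         c(0.85, 0.80)),
                         allow_swap = FALSE) {
  out <- lapply(brackets, function(b) {
    categorize(map, stack, calibration_presences, independent_presences,
               high_capture = b[1L], moderate_capture = b[2L],
               allow_swap = allow_swap)
  })
  names(out) <- vapply(brackets,
                       function(b) paste0("h", b[1L], "_m", b[2L]), "")
  out
}
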