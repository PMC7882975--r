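#' Presence-background ROC AUC
#'
#' Rank AUC for presence-only models: the x-axis is the proportion of
#' background scored at or above a threshold (rather than a false-positive
#' rate over true absences), the y-axis the proportion of presences at or
#' above it. The curve is swept over every distinct score and
#' trapezoid-integrated, which equals the Mann-Whitney statistic
#' `P(score_presence > score_background) + P(tie)/2`.
#'
#' `bounds` optionally restricts integration to a background-proportion
#' interval (a partial-area variant), rescaled by the interval width; the
#' default `c(0, 1)` is the full-range statistic.
#'
#' @param scores_presence,scores_background Non-empty numeric score vectors.
#' @param bounds Length-2 increasing vector within `[0, 1]`.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' auc_presence_background(c(0.9, 0.8), c(0.7, 0.85)) # 0.75
auc_presence_background <- function(scores_presence, scores_background,
                                    bounds = c(0, 1)) {
  sp <- scores_presence[!is.na(scores_presence)]
  sb <- scores_background[!is.na(scores_background)]
  if (!length(sp) || !length(sb)) stop("empty score vector")
  stopifnot(length(bounds) == 2L, bounds[1L] < bounds[2L],
            bounds[1L] >= 0, bounds[2L] <= 1)
  spo <- sort(sp); sbo <- sort(sb)
  thr <- sort(unique(c(sp, sb)), decreasing = TRUE)
  # fraction >= threshold, swept from the highest score down
  y <- (length(sp) - findInterval(thr, spo, left.open = TRUE)) / length(sp)
  x <- (length(sb) - findInterval(thr, sbo, left.open = TRUE)) / length(sb)
  x <- c(0, x); y <- c(0, y) # threshold above every score
  if (!identical(bounds, c(0, 1))) {
    yi <- stats::approx(x, y, xout = bounds, ties = max, rule = 2)$y
    keep <- x > bounds[1L] & x < bounds[2L]
    x <- c(bounds[1L], x[keep], bounds[2L])
    y <- c(yi[1L], y[keep], yi[2L])
  }
  a <- sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
  a / (bounds[2L] - bounds[1L])
}

#' Continuous Boyce index
#'
#' Measures calibration of a suitability surface: scores are scanned with
#' moving windows; within window `i`, `P_i` is the fraction of presence
#' scores and `E_i` the fraction of area (background) scores, and the index
#' is the Spearman rank correlation between `P_i / E_i` and the window's
#' position along the score axis. +1 means predicted-to-expected ratio rises
#' monotonically with predicted suitability (perfect monotone calibration).
#' Windows with `E_i = 0` are dropped.
#'
#' @param scores_at_presences Scores at presence locations.
#' @param scores_over_area Scores over the evaluation area (background
#'   sample or full surface).
#' @param n_windows Number of window centers (default 101).
#' @param window_width_fraction Window width as a fraction of the score range
#'   (default 0.1).
#' @return Boyce index in `[-1, 1]`.
#' @export
boyce_index <- function(scores_at_presences, scores_over_area,
                        n_windows = 101L, window_width_fraction = 0.1) {
  sp <- scores_at_presences[!is.na(scores_at_presences)]
  sa <- scores_over_area[!is.na(scores_over_area)]
  if (!length(sp) || !length(sa)) stop("empty score vector")
  rng <- range(sa)
  if (diff(rng) <= 0)
    stop("constant score surface: Boyce index undefined; inspect predictions")
  w <- window_width_fraction * diff(rng)
  centers <- seq(rng[1L] + w / 2, rng[2L] - w / 2, length.out = n_windows)
  P <- E <- numeric(n_windows)
  for (i in seq_len(n_windows)) {
    lo <- centers[i] - w / 2; hi <- centers[i] + w / 2
    P[i] <- mean(sp >= lo & sp <= hi)
    E[i] <- mean(sa >= lo & sa <= hi)
  }
  keep <- E > 0
  if (sum(keep) < 2L) stop("fewer than 2 non-degenerate windows")
  ratio <- P[keep] / E[keep]
  suppressWarnings(stats::cor(ratio, seq_along(ratio), method = "spearman"))
}

#' Minimal predicted area
#'
#' Finds the largest threshold `t` such that at least `capture_fraction` of
#' the presence locations score at or above `t` (the lower-interpolation
#' empirical quantile of presence scores, so the capture guarantee is exact),
#' and the map area at or above that threshold. Smaller area at a given
#' capture means a more efficient model.
#'
#' @param map A `suitability_map` (see [predict.sdm_ensemble()]), or a bare
#'   numeric matrix of scores plus `cell_area`.
#' @param presence_scores Scores at presence cells.
#' @param capture_fraction In (0, 1].
#' @param cell_area Cell area (km^2) when `map` is a bare matrix.
#' @return List `threshold`, `area_km2`, `capture_fraction`.
#' @export
minimal_predicted_area <- function(map, presence_scores, capture_fraction = 0.9,
                                   cell_area = NULL) {
  stopifnot(capture_fraction > 0, capture_fraction <= 1)
  if (inherits(map, "suitability_map")) {
    vals <- map$values
    cell_area <- map$cell_area_km2
  } else {
    vals <- map
    if (is.null(cell_area)) stop("cell_area required for a bare matrix")
  }
  t <- mpa_threshold(presence_scores, capture_fraction)
  area <- sum(vals >= t, na.rm = TRUE) * cell_area
  list(threshold = t, area_km2 = area, capture_fraction = capture_fraction)
}

#' Capture-quantile threshold of a presence score vector
#'
#' The largest `t` with `mean(scores >= t) >= capture_fraction`; the order
#' statistic at rank `n - ceiling(capture * n) + 1`.
#'
#' @param scores Presence scores.
#' @param capture_fraction In (0, 1].
#' @return Threshold score.
#' @export
mpa_threshold <- function(scores, capture_fraction) {
  stopifnot(capture_fraction > 0, capture_fraction <= 1)
  s <- sort(scores[!is.na(scores)])
  n <- length(s)
  if (!n) stop("no presence scores")
  k <- n - ceiling(capture_fraction * n - 1e-9) + 1L
  s[max(k, 1L)]
}

#' Evaluate a model's predictions against one presence set
#'
#' Bundles the three validation statistics for one model x evaluation-set
#' pair: presence-background AUC, continuous Boyce index, and minimal
#' predicted area at the given capture level. Area scores for AUC and Boyce
#' come from a spatially well-distributed evaluation background drawn at
#' `background_density` (default 1 point per 10 km^2) over the evaluation
#' extent, unless an explicit `background` sample is supplied.
#'
#' @param map A `suitability_map` over the full stack.
#' @param stack The [grid_stack()].
#' @param presence_table Presence table of the evaluation set.
#' @param extent_tag Evaluation extent for the background draw.
#' @param background Optional precomputed [sample_background()] result, shared
#'   across models so AUC differences are not background noise.
#' @param background_density Points per km^2 for the evaluation background.
#' @param mpa_capture Capture level for MPA (default 0.9).
#' @param seed Integer seed for the background draw.
#' @return data.frame row: `auc`, `boyce`, `mpa_threshold`, `mpa_area_km2`,
#'   `n_presence`, `n_background`, `background_density`.
#' @export
evaluate_predictions <- function(map, stack, presence_table,
                                 extent_tag = "region", background = NULL,
                                 background_density = 1 / 10,
                                 mpa_capture = 0.9, seed = 1L) {
  if (is.null(background)) {
    background <- sample_background(stack, extent_tag,
                                    initial_density_per_km2 = background_density,
                                    seed = seed)
  }
  sp <- map$values[presence_cells(presence_table, stack)]
  sb <- map$values[background$cells]
  bo <- tryCatch(boyce_index(sp, sb), error = function(e) NA_real_)
  mpa <- minimal_predicted_area(map, sp, mpa_capture)
  data.frame(
    auc = auc_presence_background(sp, sb),
    boyce = bo,
    mpa_threshold = mpa$threshold,
    mpa_area_km2 = mpa$area_km2,
    n_presence = nrow(presence_table),
    n_background = length(background$cells),
    background_density = background$density_per_km2
  )
}
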