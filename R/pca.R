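#' PCA of the environmental space at presence cells
#'
#' Ordinates presence cells of all populations in covariate space to
#' visualize and quantify regional niche differentiation. Covariates are
#' centered and (by default) scaled to unit variance; constant covariates are
#' dropped with a warning. Component signs are fixed so each loading column's
#' largest-magnitude entry is positive, making downstream assertions stable.
#'
#' @param presences Presence table covering one or more populations.
#' @param stack A [grid_stack()].
#' @param standardize Scale covariates to unit variance (default TRUE).
#' @param ellipse_level Coverage level of per-population ellipses (default
#'   0.95).
#' @return Object of class `niche_pca`: `loadings` (orthonormal columns),
#'   `scores` (rows = presence cells; zero column means), `population`
#'   (per-row label), `variance_explained` (fractions summing to 1),
#'   `ellipses` (per population, from [confidence_ellipse()] on the first two
#'   components).
#' @export
run_pca <- function(presences, stack, standardize = TRUE,
                    ellipse_level = 0.95) {
  if (nrow(presences) < 3L) stop("need at least 3 presence cells")
  x <- covariates_at(stack, presence_cells(presences, stack))
  if (ncol(x) < 2L) stop("need at least 2 covariates")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant covariate(s): ",
            paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
    x <- x[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = standardize)
  flip <- apply(pc$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rot <- sweep(pc$rotation, 2L, flip, `*`)
  scores <- sweep(pc$x, 2L, flip, `*`)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  pops <- unique(presences$population)
  ell <- lapply(stats::setNames(pops, pops), function(p) {
    confidence_ellipse(scores[presences$population == p, 1:2, drop = FALSE],
                       level = ellipse_level)
  })
  structure(
    list(loadings = rot, scores = scores, population = presences$population,
         variance_explained = ve, ellipses = ell,
         standardize = standardize, level = ellipse_level),
    class = "niche_pca"
  )
}

#' @export
print.niche_pca <- function(x, ...) {
  cat("niche_pca: ", nrow(x$scores), " presence cells, ",
      ncol(x$loadings), " components\n", sep = "")
  cat("variance explained (first two): ",
      paste(sprintf("%.1f%%", 100 * x$variance_explained[1:2]), collapse = ", "),
      "\n", sep = "")
  cat("populations: ", paste(names(x$ellipses), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Biplot-style view of a niche PCA
#' @param x A `niche_pca`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.niche_pca <- function(x, ...) {
  pops <- names(x$ellipses)
  cols <- stats::setNames(grDevices::palette.colors(max(3L, length(pops)))[
    seq_along(pops)], pops)
  graphics::plot(x$scores[, 1:2], col = cols[x$population], pch = 16,
                 cex = 0.4,
                 xlab = sprintf("PC1 (%.0f%%)", 100 * x$variance_explained[1L]),
                 ylab = sprintf("PC2 (%.0f%%)", 100 * x$variance_explained[2L]),
                 ...)
  th <- seq(0, 2 * pi, length.out = 181)
  for (p in pops) {
    e <- x$ellipses[[p]]
    if (e$degenerate) next
    ch <- chol(e$shape)
    pts <- cbind(cos(th), sin(th)) %*% ch * sqrt(e$radius2)
    graphics::lines(pts[, 1] + e$center[1], pts[, 2] + e$center[2],
                    col = cols[p], lwd = 2)
  }
  graphics::legend("topright", legend = pops, col = cols, pch = 16, bty = "n")
  invisible(x)
}

#' Gaussian confidence ellipse of 2-D scores
#'
#' Center is the componentwise mean; the ellipse is the set
#' `(z - center)' S^{-1} (z - center) <= chisq_2(level)` with `S` the sample
#' covariance — the standard normal-theory coverage ellipse.
#'
#' @param scores_2d Matrix with 2 columns, >= 3 rows.
#' @param level Coverage level in (0, 1).
#' @return List: `center`, `shape` (2x2 covariance), `radius2`
#'   (`qchisq(level, 2)`), `level`, `area`, `degenerate` flag.
#' @export
confidence_ellipse <- function(scores_2d, level = 0.95) {
  scores_2d <- as.matrix(scores_2d)
  stopifnot(ncol(scores_2d) == 2L, level > 0, level < 1)
  if (nrow(scores_2d) < 3L) stop("need at least 3 points")
  ctr <- colMeans(scores_2d)
  S <- stats::cov(scores_2d)
  r2 <- stats::qchisq(level, df = 2)
  detS <- det(S)
  degenerate <- !is.finite(detS) || detS <= .Machine$double.eps
  list(center = ctr, shape = S, radius2 = r2, level = level,
       area = if (degenerate) 0 else pi * r2 * sqrt(detS),
       degenerate = degenerate)
}

point_in_ellipse <- function(px, py, e) {
  if (e$degenerate) return(rep(FALSE, length(px)))
  d <- cbind(px - e$center[1L], py - e$center[2L])
  stats::mahalanobis(d, center = c(0, 0), cov = e$shape) <= e$radius2
}

#' Niche proximity between two populations in PC space
#'
#' Centroid distance is Euclidean in the first two components; ellipse
#' overlap is the Jaccard fraction `area(A intersect B) / area(A union B)` of
#' the two coverage ellipses, computed by indicator integration on an
#' `n_grid x n_grid` lattice over the joint bounding box.
#'
#' @param summary A `niche_pca`.
#' @param pop_a,pop_b Population ids present in the summary.
#' @param n_grid Lattice resolution per axis (default 500).
#' @return List: `centroid_distance`, `ellipse_overlap_fraction`,
#'   `degenerate` flag.
#' @export
niche_proximity <- function(summary, pop_a, pop_b, n_grid = 500L) {
  for (p in c(pop_a, pop_b)) {
    if (!p %in% names(summary$ellipses))
      stop("population '", p, "' not in the PCA summary")
  }
  ea <- summary$ellipses[[pop_a]]
  eb <- summary$ellipses[[pop_b]]
  dist <- sqrt(sum((ea$center - eb$center)^2))
  if (ea$degenerate || eb$degenerate)
    return(list(centroid_distance = dist, ellipse_overlap_fraction = 0,
                degenerate = TRUE))
  # exact axis-aligned bounding box of each ellipse, lightly padded
  half_axis <- function(e) sqrt(diag(e$shape) * e$radius2) * 1.02
  lo <- pmin(ea$center - half_axis(ea), eb$center - half_axis(eb))
  hi <- pmax(ea$center + half_axis(ea), eb$center + half_axis(eb))
  gx <- seq(lo[1L], hi[1L], length.out = n_grid)
  gy <- seq(lo[2L], hi[2L], length.out = n_grid)
  px <- rep(gx, times = n_grid)
  py <- rep(gy, each = n_grid)
  ina <- point_in_ellipse(px, py, ea)
  inb <- point_in_ellipse(px, py, eb)
  uni <- sum(ina | inb)
  ov <- if (uni == 0) 0 else sum(ina & inb) / uni
  list(centroid_distance = dist, ellipse_overlap_fraction = ov,
       degenerate = FALSE)
}

#' Does niche proximity predict cross-population transferability?
#'
#' Spearman rank correlation between niche proximity (negative centroid
#' distance, so closer = larger) and the transfer AUC over ordered population
#' pairs. A positive value says models transfer better to populations nearby
#' in environmental space.
#'
#' @param proximities Numeric centroid distances per ordered pair (>= 3).
#' @param transfer_aucs Matching AUCs.
#' @return Spearman correlation in `[-1, 1]`.
#' @export
proximity_transfer_diagnostic <- function(proximities, transfer_aucs) {
  stopifnot(length(proximities) == length(transfer_aucs))
  if (length(proximities) < 3L) stop("need at least 3 ordered pairs")
  suppressWarnings(stats::cor(-proximities, transfer_aucs,
                              method = "spearman"))
}
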