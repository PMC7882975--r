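#' Registered SDM member algorithms
#'
#' The ensemble contract requires a set of presence-background scorers behind
#' one interface: each takes a training frame (`y` in {0,1} plus covariates)
#' and returns a calibrated score function mapping covariate rows to `[0, 1]`.
#' Six learners are registered, spanning the families used in ensemble SDM
#' practice:
#'
#' * `"glm"` — logistic regression, linear terms.
#' * `"gam"` — generalized additive model, thin-plate smooths ([mgcv::gam()]).
#' * `"spline"` — logistic regression on natural cubic spline bases
#'   (flexible adaptive-spline family).
#' * `"rf"` — random forest with probability trees ([ranger::ranger()]).
#' * `"brt"` — boosted regression trees ([xgboost::xgboost()]).
#' * `"maxent"` — penalized (lasso) logistic regression on linear plus
#'   quadratic features ([glmnet::glmnet()]), the standard presence-background
#'   approximation to Maxent.
#'
#' @return Character vector of algorithm ids.
#' @export
sdm_algorithms <- function() {
  c("glm", "gam", "spline", "rf", "brt", "maxent")
}

# Drop covariate columns that are constant over the training set; a degenerate
# covariate carries no contrast between presence and background.
drop_degenerate <- function(x) {
  keep <- apply(x, 2L, function(v) length(unique(v)) > 1L)
  if (!all(keep))
    warning("dropping degenerate covariate(s): ",
            paste(colnames(x)[!keep], collapse = ", "), call. = FALSE)
  x[, keep, drop = FALSE]
}

clamp01 <- function(p) pmin(pmax(p, 0), 1)

# Fit one registered learner; returns a closure scoring a covariate matrix.
fit_algorithm <- function(algorithm_id, x, y, seed) {
  vars <- colnames(x)
  df <- data.frame(y = y, x, check.names = FALSE)
  switch(
    algorithm_id,
    glm = {
      fit <- stats::glm(stats::reformulate(vars, "y"), data = df,
                        family = stats::binomial())
      function(newx) clamp01(unname(stats::predict(
        fit, newdata = as.data.frame(newx), type = "response")))
    },
    gam = {
      terms <- vapply(vars, function(v) {
        if (length(unique(x[, v])) >= 8L) sprintf("s(`%s`, k = 5)", v)
        else sprintf("`%s`", v)
      }, "")
      fit <- mgcv::gam(stats::as.formula(paste("y ~", paste(terms, collapse = " + "))),
                       data = df, family = stats::binomial())
      function(newx) clamp01(unname(as.vector(mgcv::predict.gam(
        fit, newdata = as.data.frame(newx), type = "response"))))
    },
    spline = {
      terms <- vapply(vars, function(v) {
        if (length(unique(x[, v])) >= 5L) sprintf("splines::ns(`%s`, df = 3)", v)
        else sprintf("`%s`", v)
      }, "")
      fit <- stats::glm(stats::as.formula(paste("y ~", paste(terms, collapse = " + "))),
                        data = df, family = stats::binomial())
      function(newx) clamp01(unname(stats::predict(
        fit, newdata = as.data.frame(newx), type = "response")))
    },
    rf = {
      df$y <- factor(df$y, levels = c(0, 1))
      fit <- ranger::ranger(stats::reformulate(vars, "y"), data = df,
                            probability = TRUE, num.trees = 100L,
                            num.threads = 1L, seed = seed)
      function(newx) {
        p <- stats::predict(fit, data = as.data.frame(newx),
                            num.threads = 1L)$predictions
        clamp01(unname(p[, "1"]))
      }
    },
    brt = {
      fit <- xgboost::xgboost(
        x = as.matrix(x), y = factor(y, levels = c(0, 1)),
        objective = "binary:logistic", nrounds = 60L,
        learning_rate = 0.1, max_depth = 3L, nthreads = 1L, seed = seed
      )
      function(newx) {
        m <- as.matrix(newx)[, vars, drop = FALSE]
        p <- stats::predict(fit, m, type = "response")
        if (is.matrix(p)) p <- p[, ncol(p)]
        clamp01(unname(p))
      }
    },
    maxent = {
      feat <- function(m) {
        m <- as.matrix(m)[, vars, drop = FALSE]
        cbind(m, `colnames<-`(m^2, paste0(vars, "^2")))
      }
      lam <- c(0.1, 0.01, 0.001)
      fit <- glmnet::glmnet(feat(x), y, family = "binomial", alpha = 1,
                            lambda = lam)
      function(newx) clamp01(as.vector(stats::predict(
        fit, newx = feat(newx), s = 0.001, type = "response")))
    },
    stop("unknown algorithm id: ", algorithm_id)
  )
}

#' Fit a single ensemble member
#'
#' Fits one registered algorithm on one presence set against one background
#' draw, attaches the member's training AUC (computed by
#' [auc_presence_background()] on the member's own presence/background
#' scores), and returns a `fitted_member`.
#'
#' @param algorithm_id One of [sdm_algorithms()].
#' @param presence_x,background_x Covariate matrices (rows = cells).
#' @param seed Integer seed for stochastic learners.
#' @param replicate_id Background replicate index carried for bookkeeping.
#' @return `fitted_member`: list with `algorithm_id`, `replicate_id`,
#'   `score` (closure), `member_auc`.
#' @export
fit_member <- function(algorithm_id, presence_x, background_x, seed = 1L,
                       replicate_id = 1L) {
  if (nrow(presence_x) < 20L || nrow(background_x) < 20L)
    stop("need at least 20 presence and 20 background cells")
  x <- rbind(presence_x, background_x)
  x <- drop_degenerate(x)
  if (ncol(x) == 0L) stop("no non-degenerate covariates left")
  y <- c(rep(1L, nrow(presence_x)), rep(0L, nrow(background_x)))
  score <- fit_algorithm(algorithm_id, x, y, seed)
  s_all <- score(x)
  structure(
    list(algorithm_id = algorithm_id, replicate_id = replicate_id,
         score = score, covariates = colnames(x),
         member_auc = auc_presence_background(s_all[y == 1L], s_all[y == 0L])),
    class = "fitted_member"
  )
}

#' Median-inclusion, AUC-proportional ensemble weights
#'
#' The ensemble combination rule: a member is included iff its AUC is greater
#' than or equal to the median AUC over all members (median of an even count
#' is the mean of the two middle values; ties at the median are included), and
#' included members get weights proportional to their raw AUC, normalized to
#' sum to 1.
#'
#' @param member_aucs Numeric vector of member AUCs.
#' @return List `included` (logical) and `weights` (numeric, sums to 1).
#' @export
#' @examples
#' ensemble_weights(c(0.9, 0.8, 0.7, 0.6)) # weights 9/17, 8/17, 0, 0
ensemble_weights <- function(member_aucs) {
  stopifnot(length(member_aucs) >= 1L, all(is.finite(member_aucs)))
  med <- stats::median(member_aucs)
  included <- member_aucs >= med
  w <- ifelse(included, member_aucs, 0)
  if (sum(w) == 0) w <- as.numeric(included) # all-zero AUCs: equal weights
  list(included = included, weights = w / sum(w))
}

#' Fit an AUC-weighted presence-background ensemble
#'
#' The package's central model. For each of `n_replicates` background
#' replicates, a fresh background of size equal to the number of presence
#' cells is drawn from the stated extent (two-stage density sampling,
#' [sample_background()]); every registered algorithm is fitted on each
#' replicate, giving `length(algorithms) * n_replicates` members. Members are
#' combined by [ensemble_weights()]: inclusion at or above the median member
#' AUC, weights proportional to AUC.
#'
#' @param presences Presence table (see [aggregate_to_cells()]), one
#'   population or several combined.
#' @param stack A [grid_stack()].
#' @param extent_tag Background extent: a region label or `"region"`.
#' @param algorithms Subset of [sdm_algorithms()].
#' @param n_replicates Background replicates per algorithm (>= 1).
#' @param background_density Stage-one pool density (points per km^2) for
#'   background draws; default 1 point per 1.5 km^2.
#' @param seed Integer seed; all background draws and stochastic learners
#'   derive sub-streams from it.
#' @return An object of class `sdm_ensemble` with components `members`,
#'   `included`, `weights`, `member_aucs`, plus fitting metadata. Methods:
#'   [print.sdm_ensemble()], [summary.sdm_ensemble()],
#'   [predict.sdm_ensemble()], [plot.sdm_ensemble()],
#'   [weights.sdm_ensemble()].
#' @export
fit_sdm_ensemble <- function(presences, stack, extent_tag = "region",
                             algorithms = sdm_algorithms(),
                             n_replicates = 10L,
                             background_density = 1 / 1.5,
                             seed = 1L) {
  stopifnot(n_replicates >= 1L, length(algorithms) >= 1L)
  unknown <- setdiff(algorithms, sdm_algorithms())
  if (length(unknown))
    stop("unregistered algorithm(s): ", paste(unknown, collapse = ", "))
  n <- nrow(presences)
  pres_cells <- presence_cells(presences, stack)
  px <- covariates_at(stack, pres_cells)
  members <- vector("list", length(algorithms) * n_replicates)
  k <- 0L
  for (r in seq_len(n_replicates)) {
    bg <- sample_background(stack, extent_tag,
                            initial_density_per_km2 = background_density,
                            target_n = n,
                            seed = substream_seed(seed, paste0("replicate", r)))
    bx <- covariates_at(stack, bg$cells)
    for (a in algorithms) {
      k <- k + 1L
      members[[k]] <- fit_member(
        a, px, bx, replicate_id = r,
        seed = substream_seed(seed, paste0("member_", a, "_", r))
      )
    }
  }
  aucs <- vapply(members, `[[`, 0, "member_auc")
  rule <- ensemble_weights(aucs)
  structure(
    list(members = members, member_aucs = aucs,
         included = rule$included, weights = rule$weights,
         algorithms = algorithms, n_replicates = n_replicates,
         extent_tag = extent_tag, covariate_names = names(stack$layers),
         n_presences = n, background_density = background_density,
         seed = seed, call = match.call()),
    class = "sdm_ensemble"
  )
}

#' @export
print.sdm_ensemble <- function(x, ...) {
  cat("sdm_ensemble: ", length(x$members), " members (",
      length(x$algorithms), " algorithms x ", x$n_replicates,
      " background replicates), ", sum(x$included), " included\n", sep = "")
  cat("presences: ", x$n_presences, ", background extent: '", x$extent_tag,
      "'\n", sep = "")
  cat("member AUC: median ", format(stats::median(x$member_aucs), digits = 3),
      ", range [", format(min(x$member_aucs), digits = 3), ", ",
      format(max(x$member_aucs), digits = 3), "]\n", sep = "")
  invisible(x)
}

#' Summarize an ensemble: per-algorithm member AUCs and weights
#'
#' @param object An `sdm_ensemble`.
#' @param ... Unused.
#' @return data.frame, one row per member: `algorithm`, `replicate`,
#'   `member_auc`, `included`, `weight`.
#' @export
summary.sdm_ensemble <- function(object, ...) {
  out <- data.frame(
    algorithm = vapply(object$members, `[[`, "", "algorithm_id"),
    replicate = vapply(object$members, `[[`, 0L, "replicate_id"),
    member_auc = object$member_aucs,
    included = object$included,
    weight = object$weights
  )
  class(out) <- c("summary.sdm_ensemble", "data.frame")
  out
}

#' @export
print.summary.sdm_ensemble <- function(x, ...) {
  cat("ensemble members (inclusion at >= median AUC, weights ∝ AUC):\n")
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Normalized member weights of an ensemble
#' @param object An `sdm_ensemble`.
#' @param ... Unused.
#' @return Named numeric vector summing to 1.
#' @export
weights.sdm_ensemble <- function(object, ...) {
  stats::setNames(object$weights,
                  paste0(vapply(object$members, `[[`, "", "algorithm_id"),
                         "_r", vapply(object$members, `[[`, 0L, "replicate_id")))
}

#' Predict ensemble suitability
#'
#' With `newdata` a covariate matrix/data.frame, returns the per-row ensemble
#' score: the weighted average of included members' scores, a convex
#' combination always inside the envelope of member scores. With a
#' [grid_stack()], scores every cell and returns a `suitability_map`.
#'
#' @param object An `sdm_ensemble`.
#' @param newdata Covariate matrix/data.frame, or a `grid_stack`.
#' @param ... Unused.
#' @return Numeric vector, or a `suitability_map` (list: `values` matrix,
#'   `cell_area_km2`, `provenance`).
#' @export
predict.sdm_ensemble <- function(object, newdata, ...) {
  if (inherits(newdata, "grid_stack")) {
    missing_cov <- setdiff(object$covariate_names, names(newdata$layers))
    if (length(missing_cov))
      stop("stack lacks covariate(s): ", paste(missing_cov, collapse = ", "))
    d <- dim(newdata)
    x <- covariates_at(newdata, seq_len(prod(d)))
    s <- predict(object, x)
    return(structure(
      list(values = matrix(s, d[1L], d[2L]),
           cell_area_km2 = cell_area_km2(newdata),
           provenance = list(extent_tag = object$extent_tag,
                             seed = object$seed)),
      class = "suitability_map"
    ))
  }
  x <- as.matrix(newdata)
  s <- numeric(nrow(x))
  for (i in which(object$included)) {
    s <- s + object$weights[i] * object$members[[i]]$score(x)
  }
  s
}

#' @export
print.suitability_map <- function(x, ...) {
  cat("suitability_map: ", nrow(x$values), " x ", ncol(x$values),
      " cells, scores in [", format(min(x$values), digits = 3), ", ",
      format(max(x$values), digits = 3), "]\n", sep = "")
  invisible(x)
}

#' Plot an ensemble's predicted surface
#' @param x An `sdm_ensemble`.
#' @param stack The [grid_stack()] to predict over.
#' @param ... Passed to [graphics::image()].
#' @export
plot.sdm_ensemble <- function(x, stack, ...) {
  map <- predict(x, stack)
  plot(map, main = "ensemble suitability", ...)
  invisible(map)
}

#' @export
plot.suitability_map <- function(x, ...) {
  graphics::image(t(x$values)[, rev(seq_len(nrow(x$values)))],
                  useRaster = TRUE, axes = FALSE,
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Permutation importance of covariates in an ensemble
#'
#' For each included member and each covariate, predictions over the
#' evaluation cells are recomputed with that covariate's column randomly
#' permuted; importance is `1 - Pearson r` between permuted and original
#' predictions, averaged over `n_permutations` shuffles. An unused covariate
#' leaves predictions unchanged (importance 0); a constant prediction vector
#' makes the correlation undefined and is reported as importance 0 with a
#' warning. Per-member values are aggregated as their mean per covariate.
#'
#' @param ensemble An `sdm_ensemble`.
#' @param eval_x Covariate matrix of evaluation cells (>= 30 rows).
#' @param n_permutations Shuffles averaged per (member, covariate).
#' @param seed Integer seed.
#' @return List of class `permutation_importance`: `per_member` (long
#'   data.frame) and `aggregated` (covariate, importance; sorted decreasing).
#' @export
permutation_importance <- function(ensemble, eval_x, n_permutations = 3L,
                                   seed = 1L) {
  x <- as.matrix(eval_x)
  if (nrow(x) < 30L) stop("need at least 30 evaluation cells")
  set.seed(substream_seed(seed, "permutation_importance"))
  idx <- which(ensemble$included)
  rows <- list()
  for (i in idx) {
    m <- ensemble$members[[i]]
    orig <- m$score(x)
    for (v in colnames(x)) {
      if (!v %in% m$covariates) {
        # member never saw this covariate: permuting it cannot change
        # predictions, so its importance is exactly 0
        rows[[length(rows) + 1L]] <- data.frame(
          covariate = v, algorithm = m$algorithm_id,
          replicate = m$replicate_id, importance = 0)
        next
      }
      imp <- numeric(n_permutations)
      for (p in seq_len(n_permutations)) {
        xp <- x
        xp[, v] <- xp[sample.int(nrow(x)), v]
        pred <- m$score(xp)
        if (stats::sd(pred) == 0 || stats::sd(orig) == 0) {
          warning("constant prediction vector; importance set to 0",
                  call. = FALSE)
          imp[p] <- 0
        } else {
          imp[p] <- 1 - stats::cor(orig, pred)
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = v, algorithm = m$algorithm_id,
        replicate = m$replicate_id, importance = mean(imp)
      )
    }
  }
  per_member <- do.call(rbind, rows)
  agg <- stats::aggregate(importance ~ covariate, per_member, mean)
  agg <- agg[order(-agg$importance), , drop = FALSE]
  rownames(agg) <- NULL
  structure(list(per_member = per_member, aggregated = agg),
            class = "permutation_importance")
}

#' @export
print.permutation_importance <- function(x, ...) {
  cat("permutation importance (1 - r between permuted and original predictions):\n")
  print.data.frame(x$aggregated, digits = 3, row.names = FALSE)
  invisible(x)
}
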