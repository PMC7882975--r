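# Shared toy training sets
sep_data <- function(n = 40, seed = 1) {
  set.seed(seed)
  list(px = cbind(cov1 = rnorm(n, 2, 0.1)),
       bx = cbind(cov1 = rnorm(n, -2, 0.1)))
}

test_that("every registered algorithm separates a separable toy problem", {
  d <- sep_data()
  for (a in sdm_algorithms()) {
    m <- fit_member(a, d$px, d$bx, seed = 7)
    expect_equal(m$member_auc, 1.0, tolerance = 1e-9)
    expect_true(all(m$score(d$px) >= 0 & m$score(d$px) <= 1))
  }
})

test_that("shuffled labels give chance-level member AUC", {
  set.seed(2)
  x <- cbind(cov1 = rnorm(500), cov2 = rnorm(500))
  sh <- sample(500)
  m <- fit_member("glm", x[sh[1:250], , drop = FALSE],
                  x[sh[251:500], , drop = FALSE], seed = 1)
  expect_gt(m$member_auc, 0.4)
  expect_lt(m$member_auc, 0.6)
})

test_that("stochastic learners are deterministic under a fixed seed", {
  set.seed(3)
  px <- cbind(cov1 = rnorm(60, 1), cov2 = rnorm(60))
  bx <- cbind(cov1 = rnorm(60), cov2 = rnorm(60, 0.5))
  for (a in c("rf", "brt")) {
    m1 <- fit_member(a, px, bx, seed = 5)
    m2 <- fit_member(a, px, bx, seed = 5)
    expect_identical(m1$member_auc, m2$member_auc)
  }
})

test_that("degenerate covariates are dropped with a warning, not an error", {
  set.seed(4)
  px <- cbind(cov1 = rnorm(30, 2), flat = rep(1, 30))
  bx <- cbind(cov1 = rnorm(30, -2), flat = rep(1, 30))
  expect_warning(m <- fit_member("glm", px, bx, seed = 1), "degenerate")
  expect_equal(m$covariates, "cov1")
  expect_equal(m$member_auc, 1.0)
})

test_that("small training sets are refused", {
  d <- sep_data(n = 10)
  expect_error(fit_member("glm", d$px, d$bx), "at least 20")
})

test_that("median-inclusion AUC weighting follows the combination rule", {
  r <- ensemble_weights(c(0.9, 0.8, 0.7, 0.6))
  expect_identical(r$included, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$weights, c(9 / 17, 8 / 17, 0, 0))
  # all equal: everyone included at equal weight
  r2 <- ensemble_weights(rep(0.8, 5))
  expect_true(all(r2$included))
  expect_equal(r2$weights, rep(0.2, 5))
  # property: weights sum to 1; excluded iff strictly below the median
  set.seed(12)
  for (i in 1:50) {
    a <- round(runif(sample(2:60, 1)), 2)
    r <- ensemble_weights(a)
    expect_equal(sum(r$weights), 1, tolerance = 1e-12)
    expect_identical(r$included, a >= median(a))
    expect_true(all((r$weights > 0) == r$included | sum(a[r$included]) == 0))
  }
})

test_that("an ensemble fits algorithms x replicates members with unit weight", {
  w <- small_world(seed = 2)
  ens <- fit_sdm_ensemble(w$calibration$west, w$stack, extent_tag = "west",
                          algorithms = c("glm", "spline"), n_replicates = 3,
                          seed = 4)
  expect_s3_class(ens, "sdm_ensemble")
  expect_length(ens$members, 6L)
  expect_equal(sum(ens$weights), 1, tolerance = 1e-12)
  expect_identical(ens$included, ens$member_aucs >= median(ens$member_aucs))
  expect_true(all(ens$weights[!ens$included] == 0))
  # summary and weights methods agree with the internals
  s <- summary(ens)
  expect_equal(nrow(s), 6L)
  expect_equal(s$weight, ens$weights)
  expect_equal(unname(weights(ens)), ens$weights)
})

test_that("ensemble prediction is a convex combination of included members", {
  w <- small_world(seed = 5)
  ens <- fit_sdm_ensemble(w$calibration$central, w$stack,
                          extent_tag = "central",
                          algorithms = c("glm", "spline", "rf"),
                          n_replicates = 2, seed = 6)
  cells <- sample(prod(dim(w$stack)), 300)
  x <- covariates_at(w$stack, cells)
  s <- predict(ens, x)
  member_scores <- vapply(ens$members[ens$included],
                          function(m) m$score(x), numeric(300))
  expect_true(all(s >= apply(member_scores, 1, min) - 1e-9))
  expect_true(all(s <= apply(member_scores, 1, max) + 1e-9))
  expect_true(all(s >= 0 & s <= 1))
  # weighted-average identity against a direct recomputation
  expect_equal(s, as.vector(member_scores %*% ens$weights[ens$included]),
               tolerance = 1e-12)
})

test_that("a single-member ensemble predicts exactly that member", {
  w <- small_world(seed = 7)
  ens <- fit_sdm_ensemble(w$calibration$east, w$stack, extent_tag = "east",
                          algorithms = "glm", n_replicates = 1, seed = 2)
  expect_true(all(ens$included))
  map <- predict(ens, w$stack)
  x <- covariates_at(w$stack, seq_len(prod(dim(w$stack))))
  expect_equal(as.vector(map$values), ens$members[[1]]$score(x),
               tolerance = 1e-12)
})

test_that("refitting with the same seed reproduces the ensemble exactly", {
  w <- small_world(seed = 8)
  e1 <- fit_sdm_ensemble(w$calibration$west, w$stack, extent_tag = "west",
                         algorithms = c("glm", "rf"), n_replicates = 2,
                         seed = 11)
  e2 <- fit_sdm_ensemble(w$calibration$west, w$stack, extent_tag = "west",
                         algorithms = c("glm", "rf"), n_replicates = 2,
                         seed = 11)
  expect_identical(e1$member_aucs, e2$member_aucs)
  expect_identical(predict(e1, w$stack)$values, predict(e2, w$stack)$values)
})

test_that("prediction refuses a stack lacking a training covariate", {
  w <- small_world(seed = 9)
  ens <- fit_sdm_ensemble(w$calibration$west, w$stack, extent_tag = "west",
                          algorithms = "glm", n_replicates = 1, seed = 1)
  crippled <- grid_stack(w$stack$layers[-2], region_labels = w$stack$region_labels)
  expect_error(predict(ens, crippled), names(w$stack$layers)[2])
})

test_that("ensemble training AUC is not materially below its members'", {
  # the combination should not damage discrimination relative to the
  # weakest included member
  ok <- TRUE
  for (s in 1:20) {
    w <- small_world(seed = s)
    tab <- w$calibration$central
    ens <- fit_sdm_ensemble(tab, w$stack, extent_tag = "central",
                            algorithms = c("glm", "spline"),
                            n_replicates = 1, seed = s)
    bg <- sample_background(w$stack, "central", 1 / 2, target_n = nrow(tab),
                            seed = s + 1000)
    px <- covariates_at(w$stack, presence_cells(tab, w$stack))
    bx <- covariates_at(w$stack, bg$cells)
    ens_auc <- auc_presence_background(predict(ens, px), predict(ens, bx))
    mem_auc <- vapply(ens$members[ens$included], function(m)
      auc_presence_background(m$score(px), m$score(bx)), 0)
    if (ens_auc < min(mem_auc) - 0.02) ok <- FALSE
  }
  expect_true(ok)
})

test_that("permutation importance flags used covariates and zeroes unused ones", {
  set.seed(21)
  n <- 200
  x <- cbind(cov1 = rnorm(n), cov2 = rnorm(n))
  # member trained on cov1 only
  m <- fit_member("glm", cbind(cov1 = rnorm(60, 2)),
                  cbind(cov1 = rnorm(60, -2)), seed = 1)
  ens <- structure(
    list(members = list(m), member_aucs = m$member_auc, included = TRUE,
         weights = 1, algorithms = "glm", n_replicates = 1,
         extent_tag = "region", covariate_names = c("cov1", "cov2"),
         n_presences = 60, background_density = 1, seed = 1),
    class = "sdm_ensemble")
  imp <- permutation_importance(ens, x, n_permutations = 2, seed = 9)
  agg <- imp$aggregated
  expect_equal(agg$importance[agg$covariate == "cov2"], 0)
  expect_gt(agg$importance[agg$covariate == "cov1"], 0.2)
})

test_that("permutation importance matches a direct recomputation", {
  set.seed(22)
  d <- sep_data(n = 50, seed = 3)
  m <- fit_member("glm", d$px, d$bx, seed = 1)
  ens <- structure(
    list(members = list(m), member_aucs = m$member_auc, included = TRUE,
         weights = 1, algorithms = "glm", n_replicates = 1,
         extent_tag = "region", covariate_names = "cov1",
         n_presences = 50, background_density = 1, seed = 1),
    class = "sdm_ensemble")
  x <- cbind(cov1 = rnorm(100))
  imp <- permutation_importance(ens, x, n_permutations = 1, seed = 5)
  # oracle: replay the internal RNG stream for the single shuffle
  set.seed(substream_seed(5, "permutation_importance"))
  idx <- sample.int(100)
  xp <- x; xp[, 1] <- xp[idx, 1]
  oracle <- 1 - cor(m$score(x), m$score(xp))
  expect_equal(imp$per_member$importance, oracle, tolerance = 1e-12)
})

test_that("constant predictions yield zero importance with a warning", {
  set.seed(23)
  d <- sep_data(n = 40, seed = 4)
  m <- fit_member("glm", d$px, d$bx, seed = 1)
  ens <- structure(
    list(members = list(m), member_aucs = m$member_auc, included = TRUE,
         weights = 1, algorithms = "glm", n_replicates = 1,
         extent_tag = "region", covariate_names = "cov1",
         n_presences = 40, background_density = 1, seed = 1),
    class = "sdm_ensemble")
  x <- cbind(cov1 = rep(0.5, 50)) # constant scores; permuting is a no-op
  expect_warning(imp <- permutation_importance(ens, x, n_permutations = 1,
                                               seed = 2), "constant")
  expect_equal(imp$aggregated$importance, 0)
})

test_that("unregistered algorithms are refused", {
  w <- small_world(seed = 10)
  expect_error(fit_sdm_ensemble(w$calibration$west, w$stack,
                                algorithms = "cart", seed = 1),
               "unregistered")
})
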