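test_that("white-noise layers are standardized and reproducible", {
  st <- generate_covariate_stack(2, c(100, 100), autocorr_range_cells = 0,
                                 seed = 42)
  for (m in st$layers) {
    expect_gt(var(as.vector(m)), 0.9)
    expect_lt(var(as.vector(m)), 1.1)
    expect_equal(mean(m), 0, tolerance = 1e-12)
  }
  st2 <- generate_covariate_stack(2, c(100, 100), autocorr_range_cells = 0,
                                  seed = 42)
  expect_identical(st$layers, st2$layers)
  st3 <- generate_covariate_stack(2, c(100, 100), autocorr_range_cells = 0,
                                  seed = 43)
  expect_false(identical(st$layers, st3$layers))
})

test_that("requested inter-covariate correlation is realized", {
  st <- generate_covariate_stack(2, c(100, 100), autocorr_range_cells = 0,
                                 inter_covariate_correlation = 0.6, seed = 7)
  r <- cor(as.vector(st$layers[[1]]), as.vector(st$layers[[2]]))
  expect_gt(r, 0.5)
  expect_lt(r, 0.7)
})

test_that("correlations beyond the |0.7| screening bound are rejected", {
  expect_error(
    generate_covariate_stack(2, c(32, 32), inter_covariate_correlation = 0.8),
    "0.7"
  )
  expect_error(
    generate_covariate_stack(3, c(32, 32), inter_covariate_correlation = -0.3),
    "negative"
  )
})

test_that("autocorrelated layers remain standardized", {
  st <- generate_covariate_stack(2, c(80, 80), autocorr_range_cells = 5,
                                 seed = 3)
  for (m in st$layers) {
    expect_equal(var(as.vector(m)), 1, tolerance = 1e-9)
    # smoothing induces positive lag-1 correlation
    expect_gt(cor(as.vector(m[, -1]), as.vector(m[, -ncol(m)])), 0.5)
  }
})

test_that("suitability follows the Gaussian-response closed forms", {
  flat <- function(x) matrix(x, 16, 16)
  st <- manual_stack(list(cov1 = flat(1)))
  ns <- niche_spec("p", optimum = c(cov1 = 0), breadth = c(cov1 = 1),
                   weight = c(cov1 = 2), baseline_prevalence = 0.5)
  f <- make_suitability(st, ns)
  expect_equal(f$values[1, 1], plogis(2 * exp(-0.5) - 1), tolerance = 1e-12)
  expect_equal(f$values[1, 1], 0.5530647, tolerance = 1e-6)

  # at the optimum the field peaks at logistic(sum(w)/2)
  st0 <- manual_stack(list(cov1 = flat(0)))
  f0 <- make_suitability(st0, ns)
  expect_equal(f0$values[1, 1], plogis(2 / 2), tolerance = 1e-12)

  # zero weights give a uniform field at the baseline prevalence
  ns0 <- niche_spec("p", optimum = c(cov1 = 0), breadth = c(cov1 = 1),
                    weight = c(cov1 = 0), baseline_prevalence = 0.3)
  v0 <- make_suitability(st, ns0)$values
  expect_equal(range(v0), c(0.3, 0.3), tolerance = 1e-12)
})

test_that("suitability is bounded and decays away from the optimum", {
  grad <- matrix(seq(-3, 3, length.out = 32), 32, 32)
  st <- manual_stack(list(cov1 = grad))
  ns <- niche_spec("p", optimum = c(cov1 = 0.5), breadth = c(cov1 = 0.8),
                   weight = c(cov1 = 3))
  f <- make_suitability(st, ns)
  expect_true(all(f$values > 0 & f$values < 1))
  x <- grad[1, ]
  s <- f$values[1, ]
  ord <- order(abs(x - 0.5))
  expect_true(all(diff(s[ord]) <= 1e-12))
})

test_that("unknown niche covariates are reported by name", {
  st <- manual_stack(list(cov1 = matrix(0, 16, 16)))
  ns <- niche_spec("p", optimum = c(covX = 0), breadth = c(covX = 1),
                   weight = c(covX = 1))
  expect_error(make_suitability(st, ns), "covX")
})

test_that("zero home-range dispersion pins every fix to its collar cell", {
  st <- manual_stack(list(cov1 = matrix(0, 20, 20)))
  f <- structure(list(values = matrix(0.8, 20, 20), population_id = "p"),
                 class = "suitability_field")
  locs <- sample_gps_presences(f, st, n_collars = 6, fixes_per_collar = 30,
                               home_range_sd_cells = 0, seed = 5,
                               region = "region")
  per_collar <- split(locs, locs$collar_id)
  for (g in per_collar) {
    expect_equal(length(unique(ceiling(g$x))), 1L)
    expect_equal(length(unique(ceiling(g$y))), 1L)
  }
})

test_that("gps sampling is seed-reproducible", {
  st <- generate_covariate_stack(2, c(40, 40), seed = 1)
  ns <- niche_spec("p", optimum = c(cov1 = 0), breadth = c(cov1 = 1),
                   weight = c(cov1 = 2))
  f <- make_suitability(st, ns)
  a <- sample_gps_presences(f, st, 4, 50, 3, seed = 9, region = "region")
  b <- sample_gps_presences(f, st, 4, 50, 3, seed = 9, region = "region")
  expect_identical(a, b)
  c_ <- sample_gps_presences(f, st, 4, 50, 3, seed = 10, region = "region")
  expect_false(identical(a, c_))
})

test_that("rejection sampling accepts fixes in proportion to suitability", {
  # checkerboard 0.8/0.2 with a wide home range exposes both levels equally;
  # accepted fixes should split ~4:1
  f <- checkerboard_field(40, 40, 0.2, 0.8)
  st <- manual_stack(list(cov1 = matrix(0, 40, 40)))
  locs <- sample_gps_presences(f, st, n_collars = 1, fixes_per_collar = 20000,
                               home_range_sd_cells = 12, seed = 11,
                               region = "region")
  lev <- f$values[cbind(ceiling(locs$y), ceiling(locs$x))]
  p_hi <- mean(lev == 0.8)
  se <- sqrt(0.8 * 0.2 / nrow(locs))
  expect_lt(abs(p_hi - 0.8), 4 * se + 0.01)
})

test_that("independent points are suitability-proportional at broadening 1", {
  f <- two_level_field(40, 40, 0.1, 0.9)
  st <- manual_stack(list(cov1 = matrix(0, 40, 40)))
  locs <- sample_independent_points(f, st, n = 20000, broadening = 1,
                                    seed = 2)
  lev <- f$values[cbind(ceiling(locs$y), ceiling(locs$x))]
  p_hi <- mean(lev == 0.9)
  se <- sqrt(0.9 * 0.1 / 20000)
  expect_lt(abs(p_hi - 0.9), 4 * se + 0.01)
})

test_that("broadening near zero flattens sampling toward uniform", {
  f <- two_level_field(40, 40, 0.1, 0.9)
  st <- manual_stack(list(cov1 = matrix(0, 40, 40)))
  locs <- sample_independent_points(f, st, n = 20000, broadening = 0.01,
                                    seed = 3)
  lev <- f$values[cbind(ceiling(locs$y), ceiling(locs$x))]
  expect_lt(abs(mean(lev == 0.9) - 0.5), 0.02)
  # and the draw is reproducible
  locs2 <- sample_independent_points(f, st, n = 20000, broadening = 0.01,
                                     seed = 3)
  expect_identical(locs, locs2)
})

test_that("empirical presence density converges to the suitability field", {
  set.seed(1)
  v <- matrix(runif(100, 0.05, 0.95), 10, 10)
  f <- structure(list(values = v, population_id = "p"),
                 class = "suitability_field")
  st <- manual_stack(list(cov1 = matrix(0, 10, 10)))
  locs <- sample_independent_points(f, st, n = 50000, broadening = 1, seed = 4)
  counts <- table(factor(paste(ceiling(locs$y), ceiling(locs$x)),
                         levels = paste(c(row(v)), c(col(v)))))
  p <- as.vector(v) / sum(v)
  gof <- suppressWarnings(chisq.test(as.vector(counts), p = p))
  expect_gt(gof$p.value, 0.01)
})

test_that("niche separation grows monotonically with optimum offset", {
  st <- generate_covariate_stack(2, c(48, 48), autocorr_range_cells = 2,
                                 seed = 6)
  base <- niche_spec("a", optimum = c(cov1 = 0), breadth = c(cov1 = 1),
                     weight = c(cov1 = 3))
  fa <- make_suitability(st, base)
  sep <- vapply(c(0, 0.5, 1, 1.5, 2), function(off) {
    nb <- niche_spec("b", optimum = c(cov1 = off), breadth = c(cov1 = 1),
                     weight = c(cov1 = 3))
    mean(abs(make_suitability(st, nb)$values - fa$values))
  }, 0)
  expect_equal(sep[1], 0)
  expect_true(all(diff(sep) > 0))
})

test_that("region partitions and extent lookups behave", {
  lab <- default_region_partition(c(20, 30), c("a", "b", "c"))
  expect_equal(dim(lab), c(20, 30))
  expect_setequal(unique(as.vector(lab)), c("a", "b", "c"))
  expect_equal(sum(lab == "a"), 20 * 10)
  st <- manual_stack(list(cov1 = matrix(0, 20, 30)), region_labels = lab)
  expect_length(extent_cells(st, "b"), 200)
  expect_length(extent_cells(st, "region"), 600)
  expect_error(extent_cells(st, "nope"), "no cells")
})
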