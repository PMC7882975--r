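# Shared fixtures, built in code at test time.

# A small stack from explicit layer matrices (no simulation).
manual_stack <- function(layers, cell_size_km = 1, region_labels = NULL) {
  grid_stack(layers, cell_size_km = cell_size_km, region_labels = region_labels)
}

# Two-level suitability field: left half `lo`, right half `hi`.
two_level_field <- function(nr, nc, lo, hi, population_id = "pop") {
  v <- matrix(lo, nr, nc)
  v[, (nc %/% 2 + 1):nc] <- hi
  structure(list(values = v, population_id = population_id),
            class = "suitability_field")
}

# Checkerboard suitability field alternating lo/hi cell by cell.
checkerboard_field <- function(nr, nc, lo, hi, population_id = "pop") {
  v <- matrix(lo, nr, nc)
  v[(row(v) + col(v)) %% 2 == 0] <- hi
  structure(list(values = v, population_id = population_id),
            class = "suitability_field")
}

# Independent pair-counting AUC oracle: concordant pairs + half ties.
pair_count_auc <- function(sp, sb) {
  cmp <- outer(sp, sb, `-`)
  (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / length(cmp)
}

# Monotone P/E construction for the Boyce index: area scores on a dense
# uniform grid and presence scores from the exponential-density quantile
# transform, so every moving window holds a distinct, strictly ordered
# predicted-to-expected ratio (no lattice ties at window edges).
monotone_pe_scores <- function(lambda = 5) {
  u <- (1:20000) / 20001
  up <- log(1 + u * (exp(lambda) - 1)) / lambda
  list(area = seq(0, 1, length.out = 10000), up = up, down = 1 - up)
}

# Presence table addressing the given linear cells of a stack.
table_from_cells <- function(cells, stack, population = "pop") {
  d <- dim(stack)
  data.frame(row = (cells - 1L) %% d[1L] + 1L,
             col = (cells - 1L) %/% d[1L] + 1L,
             population = population, split = "unsplit", n_source = 1L)
}

# Small fitted world shared by ensemble/experiment tests (cheap learners).
small_world <- function(seed = 1) {
  simulate_study(seed = seed, grid_dims = c(64L, 132L),
                 n_collars = c(14L, 26L, 9L),
                 fixes_per_collar = c(45L, 80L, 25L))
}

# Large-population world used for the data-efficiency experiment: the central
# population carries >= 5,000 deduplicated presence cells.
efficiency_world <- function(seed = 1) {
  simulate_study(seed = seed, grid_dims = c(160L, 330L),
                 n_collars = c(30L, 130L, 18L),
                 fixes_per_collar = c(70L, 420L, 35L))
}
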