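#' Write and read presence tables and raw locations as CSV
#'
#' Presence tables use the fixed column set `row, col, population, split,
#' n_source`; raw location tables use `x, y, collar_id, population, error,
#' source`. Plain CSV keeps every artifact of a run diffable and
#' version-controllable.
#'
#' @param table data.frame to write.
#' @param path File path.
#' @return `write_presence_csv` returns `path` invisibly;
#'   `read_presence_csv` the data.frame.
#' @export
write_presence_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_presence_csv
#' @export
read_presence_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Serialize a grid stack to a directory of CSV layers
#'
#' Writes one headerless CSV matrix per covariate layer, one for the region
#' labels, and a `stack.json` sidecar (covariate names, grid dimensions, cell
#' size). [read_grid_stack()] restores an identical [grid_stack()].
#'
#' @param stack A [grid_stack()].
#' @param dir Directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_grid_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(stack$layers)) {
    utils::write.table(stack$layers[[nm]], file.path(dir, paste0(nm, ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  utils::write.table(stack$region_labels, file.path(dir, "region_labels.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(covariate_names = names(stack$layers),
         dims = dim(stack), cell_size_km = stack$cell_size_km),
    file.path(dir, "stack.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_grid_stack
#' @export
read_grid_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "stack.json"),
                              simplifyVector = TRUE)
  layers <- lapply(meta$covariate_names, function(nm) {
    as.matrix(utils::read.table(file.path(dir, paste0(nm, ".csv")),
                                sep = ",", header = FALSE))
  })
  names(layers) <- meta$covariate_names
  layers <- lapply(layers, function(m) {
    dimnames(m) <- NULL
    m
  })
  lab <- as.matrix(utils::read.table(file.path(dir, "region_labels.csv"),
                                     sep = ",", header = FALSE,
                                     colClasses = "character"))
  dimnames(lab) <- NULL
  grid_stack(layers, cell_size_km = meta$cell_size_km, region_labels = lab)
}

#' Serialize ensemble metadata to JSON
#'
#' Writes the member table (algorithm, replicate, AUC, inclusion, weight)
#' and fitting metadata. Member model objects are closures and are not
#' serialized; refit from the recorded seed to reproduce them exactly.
#'
#' @param ensemble An `sdm_ensemble`.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_ensemble_json <- function(ensemble, path) {
  members <- summary(ensemble)
  class(members) <- "data.frame"
  jsonlite::write_json(
    list(
      members = members,
      algorithms = ensemble$algorithms,
      n_replicates = ensemble$n_replicates,
      n_presences = ensemble$n_presences,
      extent_tag = ensemble$extent_tag,
      background_density = ensemble$background_density,
      seed = ensemble$seed
    ),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(path)
}
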