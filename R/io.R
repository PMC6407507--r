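#' @title Plain-text serialisation
#' @description Grids and tables are exchanged as plain text: climate
#'   stacks as long-format CSV (variable, row, col, value), grids as JSON,
#'   occurrence and ecoregion tables as CSV with header. (No binary raster
#'   driver is assumed to be available.)
#' @name io
NULL

#' Write / read a grid specification as JSON
#' @param grid A [grid_spec()].
#' @param path File path.
#' @export
write_grid_json <- function(grid, path) {
  x <- grid[c("n_rows", "n_cols", "cell_size", "origin_lon", "origin_lat")]
  if (!is.null(grid$nodata_mask)) x$nodata_cells <- which(grid$nodata_mask)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_grid_json
#' @export
read_grid_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  mask <- NULL
  if (!is.null(x$nodata_cells) && length(x$nodata_cells)) {
    mask <- matrix(FALSE, x$n_rows, x$n_cols)
    mask[as.integer(x$nodata_cells)] <- TRUE
  }
  grid_spec(x$n_rows, x$n_cols, x$cell_size, x$origin_lon, x$origin_lat,
            nodata_mask = mask)
}

#' Write / read a climate stack as long-format CSV
#'
#' Columns: `variable`, `row`, `col`, `value`; one record per non-NA pixel
#' per layer. The grid itself travels separately ([write_grid_json()]).
#'
#' @param stack A `climate_stack`.
#' @param path CSV path.
#' @export
write_climate_csv <- function(stack, path) {
  rows <- lapply(stack_variables(stack), function(v) {
    m <- stack$layers[[v]]
    ok <- which(!is.na(m))
    data.frame(variable = v,
               row = ((ok - 1L) %% nrow(m)) + 1L,
               col = ((ok - 1L) %/% nrow(m)) + 1L,
               value = m[ok])
  })
  data.table::fwrite(data.table::rbindlist(rows), path)
  invisible(path)
}

#' @rdname write_climate_csv
#' @param grid The [grid_spec()] the stack lives on.
#' @param scenario,gcm Labels for the reconstructed stack.
#' @export
read_climate_csv <- function(path, grid, scenario = "current", gcm = NULL) {
  d <- data.table::fread(path)
  layers <- lapply(split(d, d$variable), function(s) {
    m <- matrix(NA_real_, grid$n_rows, grid$n_cols)
    m[cbind(s$row, s$col)] <- s$value
    m
  })
  new_climate_stack(grid, layers, scenario = scenario, gcm = gcm)
}

#' Write occurrence records as CSV
#'
#' Header `species,growth_form,lon,lat` (plus any extra columns present).
#' @param table Occurrence data.frame.
#' @param path CSV path.
#' @export
write_occurrences_csv <- function(table, path) {
  data.table::fwrite(table, path)
  invisible(path)
}

#' @rdname write_occurrences_csv
#' @export
read_occurrences_csv <- function(path) {
  as.data.frame(data.table::fread(path))
}

#' Write an ecoregion map: metadata CSV + label CSV
#'
#' Metadata header `ecoregion_id,name,biome,realm`; labels as long-format
#' `row,col,ecoregion_id`.
#' @param regions An `ecoregion_map`.
#' @param meta_path,labels_path CSV paths.
#' @export
write_ecoregion_csv <- function(regions, meta_path, labels_path) {
  data.table::fwrite(regions$meta, meta_path)
  ok <- which(!is.na(regions$labels))
  data.table::fwrite(data.frame(
    row = ((ok - 1L) %% nrow(regions$labels)) + 1L,
    col = ((ok - 1L) %/% nrow(regions$labels)) + 1L,
    ecoregion_id = regions$labels[ok]), labels_path)
  invisible(meta_path)
}

#' @rdname write_ecoregion_csv
#' @param grid The [grid_spec()] the labels live on.
#' @export
read_ecoregion_csv <- function(meta_path, labels_path, grid) {
  meta <- as.data.frame(data.table::fread(meta_path))
  d <- data.table::fread(labels_path)
  labels <- matrix(NA_integer_, grid$n_rows, grid$n_cols)
  labels[cbind(d$row, d$col)] <- as.integer(d$ecoregion_id)
  new_ecoregion_map(grid, labels, meta)
}

#' Serialise / restore a fitted model as JSON
#'
#' Stores knots, weights, penalty settings, normaliser, entropy and the
#' background raw distribution, which is enough to reproduce every output
#' scale.
#' @param model A `maxent_model`.
#' @param path JSON path.
#' @export
write_model_json <- function(model, path) {
  x <- list(lambda = as.list(model$lambda), beta = model$beta,
            logZ = model$logZ, H = model$H, bg_raw = model$bg_raw,
            n_presence = model$n_presence,
            n_background = model$n_background,
            featureset = model$featureset[c("variables", "spec", "n_knots")])
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fs <- structure(list(variables = x$featureset$variables,
                       spec = lapply(x$featureset$spec, function(s) {
                         list(vmin = s$vmin, vmax = s$vmax,
                              knots = as.numeric(unlist(s$knots)))
                       }),
                       n_knots = x$featureset$n_knots),
                  class = "feature_set")
  structure(list(lambda = unlist(x$lambda), beta = x$beta, logZ = x$logZ,
                 H = x$H, bg_raw = as.numeric(x$bg_raw),
                 n_presence = x$n_presence, n_background = x$n_background,
                 featureset = fs, converged = TRUE),
            class = "maxent_model")
}

#' Restrict a climate stack to a variable subset
#'
#' @param stack A `climate_stack`.
#' @param vars Bio codes to keep (e.g. the collinearity-screened set).
#' @return A `climate_stack` with only those layers.
#' @export
subset_stack <- function(stack, vars) {
  stopifnot(all(vars %in% stack_variables(stack)))
  new_climate_stack(stack$grid, stack$layers[vars],
                    scenario = stack$scenario, gcm = stack$gcm)
}
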