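#' @title Occurrence-record quality control
#' @description The cleaning rules applied to raw occurrence tables before
#'   modelling: invalid species names, records at exactly (0, 0), records
#'   with longitude equal to latitude, and within-cell duplicates at the
#'   working grid resolution; plus the minimum-record species filter.
#' @name occ_qc
NULL

#' Default species-name validity predicate
#'
#' Accepts binomial-style names: a capitalised genus followed by one or more
#' lower-case epithets (hyphens allowed). Stands in for interactive
#' name-checking against invasive-species registries; any vectorised
#' predicate can be supplied to [clean_occurrences()] instead.
#'
#' @param name Character vector of raw names.
#' @return Logical vector.
#' @export
valid_species_name <- function(name) {
  !is.na(name) & grepl("^[A-Z][a-z]+( [a-z][a-z-]*)+$", name)
}

qc_rules <- c("bad_name", "invalid_coordinate", "zero_zero", "lon_eq_lat",
              "cell_duplicate")

#' Clean an occurrence table
#'
#' Applies the removal rules in a fixed order so that a record violating
#' several rules is tallied once, under the earliest rule:
#' bad name, invalid coordinate (non-finite or outside lon `[-180,180]` /
#' lat `[-90,90]`; an artifact addition reported separately), longitude and
#' latitude both exactly 0, longitude equal to latitude, and within-cell
#' duplicate per species at the resolution of `grid` (the first record per
#' cell in input order is kept). Cleaning is idempotent.
#'
#' @param table Data.frame with columns `species`, `lon`, `lat` and
#'   optionally `growth_form`, `name_raw` (defaults to `species`).
#' @param grid A [grid_spec()] defining the duplicate-collapse resolution.
#' @param name_predicate Vectorised predicate on `name_raw`; default
#'   [valid_species_name()].
#' @return A list with `table` (retained records) and `report` (a
#'   `qc_report`: per-rule removal counts and per-species retained counts).
#' @export
clean_occurrences <- function(table, grid,
                              name_predicate = valid_species_name) {
  stopifnot(is.data.frame(table), inherits(grid, "grid_spec"))
  if (!nrow(table)) {
    return(list(table = table,
                report = new_qc_report(stats::setNames(rep(0L, 5), qc_rules),
                                       integer(0), n_input = 0L)))
  }
  stopifnot(all(c("species", "lon", "lat") %in% names(table)))
  if (!"name_raw" %in% names(table)) table$name_raw <- table$species
  n <- nrow(table)
  removed_by <- rep(NA_character_, n)
  alive <- rep(TRUE, n)
  mark <- function(cond, rule) {
    hit <- alive & cond
    removed_by[hit] <<- rule
    alive[hit] <<- FALSE
  }
  lon <- suppressWarnings(as.numeric(table$lon))
  lat <- suppressWarnings(as.numeric(table$lat))
  mark(!name_predicate(table$name_raw), "bad_name")
  mark(!is.finite(lon) | !is.finite(lat) |
         lon < -180 | lon > 180 | lat < -90 | lat > 90, "invalid_coordinate")
  mark(lon == 0 & lat == 0, "zero_zero")
  mark(lon == lat, "lon_eq_lat")
  idx <- cell_index(grid, lon, lat)
  key <- paste(table$species, idx$row, idx$col)
  key[!alive] <- NA           # removed records must not shadow a cell
  key[is.na(idx$row)] <- NA   # outside the working grid: no cell to share
  mark(duplicated(key) & !is.na(key), "cell_duplicate")
  removed <- table(factor(removed_by, levels = qc_rules))
  kept <- table[alive, , drop = FALSE]
  per_species <- if (nrow(kept)) table(kept$species) else integer(0)
  list(table = kept,
       report = new_qc_report(stats::setNames(as.integer(removed), qc_rules),
                              per_species, n_input = n))
}

new_qc_report <- function(removed, per_species, n_input,
                          species_kept = NULL, species_dropped = NULL) {
  structure(list(removed = removed,
                 per_species = per_species,
                 n_input = n_input,
                 n_retained = n_input - sum(removed),
                 species_kept = species_kept,
                 species_dropped = species_dropped),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>", x$n_input, "records in,", x$n_retained, "retained\n")
  for (r in names(x$removed)) {
    if (x$removed[[r]] > 0) cat(sprintf("  removed %-18s %d\n", r, x$removed[[r]]))
  }
  if (!is.null(x$species_dropped) && length(x$species_dropped)) {
    cat("  species dropped by record filter:",
        paste(x$species_dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Drop species with too few cleaned records
#'
#' Species are retained only if their cleaned record count exceeds
#' `min_records` (strict inequality: the "over 100 records" reading). Set
#' `strict = FALSE` for a `>=` comparison, or `min_records = 0` for the
#' identity.
#'
#' @param table A cleaned occurrence data.frame.
#' @param min_records Record-count bound (default 100).
#' @param strict Keep species iff count `> min_records` (default) rather
#'   than `>=`.
#' @return A list with `table` (records of retained species) and `report`
#'   (per-species counts plus kept/dropped species).
#' @export
filter_species <- function(table, min_records = 100, strict = TRUE) {
  stopifnot(is.data.frame(table))
  if (!nrow(table)) {
    return(list(table = table,
                report = new_qc_report(stats::setNames(rep(0L, 5), qc_rules),
                                       integer(0), 0L,
                                       character(0), character(0))))
  }
  counts <- table(table$species)
  ok <- if (strict) counts > min_records else counts >= min_records
  kept_sp <- names(counts)[ok]
  kept <- table[table$species %in% kept_sp, , drop = FALSE]
  list(table = kept,
       report = new_qc_report(stats::setNames(rep(0L, 5), qc_rules),
                              counts, nrow(table),
                              species_kept = kept_sp,
                              species_dropped = names(counts)[!ok]))
}
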