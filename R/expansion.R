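#' @title Multi-species expansion potential
#' @description The aggregation stage: per-pixel multi-species suitability
#'   `E_j = sum_i P_ij` over retained species, current-to-future change
#'   `A_j = E_j^f - E_j^c`, zonal sums over ecoregions with the
#'   positive-change inclusion rule, biome / growth-form rollups, and the
#'   cross-scenario (moderate vs high forcing) linear regression.
#' @name expansion
NULL

#' Sum per-species suitability maps into a multi-species map
#'
#' Per-pixel sum of logistic suitability over the retained species. A
#' species with nodata at a pixel contributes 0 there (the count of such
#' holes is tallied in the `"nodata_contributions"` attribute); a pixel is
#' `NA` only where every species is `NA`.
#'
#' @param maps Non-empty list of suitability matrices (values in `[0, 1]`),
#'   all co-registered.
#' @return Matrix `E` with attribute `n_species`.
#' @export
multi_species_suitability <- function(maps) {
  if (!length(maps)) stop("empty species list")
  dims <- dim(maps[[1L]])
  stopifnot(all(vapply(maps, function(m) identical(dim(m), dims),
                       logical(1))))
  e <- matrix(0, dims[1L], dims[2L])
  n_na <- matrix(0L, dims[1L], dims[2L])
  for (m in maps) {
    na <- is.na(m)
    n_na <- n_na + na
    m[na] <- 0
    e <- e + m
  }
  e[n_na == length(maps)] <- NA_real_
  attr(e, "n_species") <- length(maps)
  attr(e, "nodata_contributions") <- n_na
  e
}

#' Change in multi-species suitability between scenarios
#'
#' `A_j = E_j^f - E_j^c` per pixel. Both maps must come from the same
#' species set (checked via the `n_species` attribute) on the same grid.
#'
#' @param future,current Multi-species maps from
#'   [multi_species_suitability()].
#' @return Change matrix `A` with attribute `n_species`.
#' @export
suitability_change <- function(future, current) {
  stopifnot(identical(dim(future), dim(current)))
  kf <- attr(future, "n_species"); kc <- attr(current, "n_species")
  if (!is.null(kf) && !is.null(kc) && kf != kc) {
    stop("species sets differ between scenarios (", kf, " vs ", kc, ")")
  }
  a <- future - current
  attr(a, "n_species") <- kf
  a
}

#' Zonal expansion potential per ecoregion
#'
#' The potential of an ecoregion is the unweighted sum of the change map
#' over its member pixels; ecoregions are included in downstream analyses
#' only when the potential is strictly positive (a potential of exactly 0
#' is excluded). Excluded ecoregions are retained in the output with
#' `included = FALSE`; ecoregions with no usable pixels get `NA` potential
#' and are flagged.
#'
#' @param change Change matrix from [suitability_change()].
#' @param regions An `ecoregion_map` co-registered with `change`.
#' @param scenario Scenario label stored on the rows.
#' @return A data.frame of class `expansion_table`: `ecoregion_id`, `name`,
#'   `biome`, `realm`, `scenario`, `n_pixels`, `potential`, `included`.
#' @export
ecoregion_potential <- function(change, regions, scenario = "RCP4.5") {
  stopifnot(inherits(regions, "ecoregion_map"),
            identical(dim(change), dim(regions$labels)))
  ok <- !is.na(change) & !is.na(regions$labels)
  sums <- tapply(change[ok], regions$labels[ok], sum)
  counts <- tapply(change[ok], regions$labels[ok], length)
  meta <- regions$meta
  pot <- rep(NA_real_, nrow(meta))
  npx <- rep(0L, nrow(meta))
  idx <- match(as.integer(names(sums)), meta$ecoregion_id)
  pot[idx] <- as.numeric(sums)
  npx[idx] <- as.integer(counts)
  out <- data.frame(ecoregion_id = meta$ecoregion_id, name = meta$name,
                    biome = meta$biome, realm = meta$realm,
                    scenario = scenario, n_pixels = npx, potential = pot,
                    included = !is.na(pot) & pot > 0,
                    stringsAsFactors = FALSE)
  out$included[is.na(pot)] <- NA
  if (anyNA(pot)) {
    warning(sum(is.na(pot)), " ecoregion(s) with no usable pixels; ",
            "potential undefined")
  }
  class(out) <- c("expansion_table", "data.frame")
  out
}

#' Group included expansion potentials by biome or growth form
#'
#' Sums the potential of included (`included == TRUE`) ecoregions within
#' each group. For growth-form grouping the input table must carry a
#' `growth_form` column (i.e. be built from per-growth-form change maps).
#'
#' @param table An `expansion_table`.
#' @param by `"biome"` or `"growth_form"`.
#' @return Data.frame: grouping column, `realm`, `scenario`, `potential`
#'   (sum over included ecoregions), `n_included`.
#' @export
group_potentials <- function(table, by = c("biome", "growth_form")) {
  by <- match.arg(by)
  stopifnot(is.data.frame(table), by %in% names(table))
  if (by == "biome") {
    bad <- setdiff(unique(table$biome),
                   c(terrestrial_biomes, freshwater_biomes))
    if (length(bad)) stop("unknown biome code(s): ",
                          paste(bad, collapse = ", "))
  }
  dt <- data.table::as.data.table(table)
  inc <- dt[dt$included %in% TRUE, ]
  keys <- c(by, "realm", "scenario")
  all_groups <- unique(dt[, keys, with = FALSE])
  agg <- inc[, list(potential = sum(potential), n_included = .N), by = keys]
  out <- merge(all_groups, agg, by = keys, all.x = TRUE)
  out$potential[is.na(out$potential)] <- 0
  out$n_included[is.na(out$n_included)] <- 0L
  as.data.frame(out)
}

#' Linear regression between the two forcing scenarios
#'
#' Ordinary least squares of the high-forcing (RCP8.5) potentials on the
#' moderate-forcing (RCP4.5) potentials, paired by ecoregion or group, with
#' the two-sided t test on the slope.
#'
#' @param potentials_rcp45,potentials_rcp85 Paired numeric vectors
#'   (length >= 3).
#' @return List: `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
scenario_regression <- function(potentials_rcp45, potentials_rcp85) {
  ok <- is.finite(potentials_rcp45) & is.finite(potentials_rcp85)
  x <- potentials_rcp45[ok]; y <- potentials_rcp85[ok]
  if (length(x) != length(potentials_rcp85[ok]) || length(x) < 3) {
    stop("need at least 3 complete pairs")
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  p <- if (nrow(sm$coefficients) < 2) NA_real_ else sm$coefficients[2L, 4L]
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = sm$r.squared, p_value = p, n = length(x))
}
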