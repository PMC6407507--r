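#' @title Synthetic-world generation
#' @description Generators for a fully known world: spatially autocorrelated
#'   bioclimatic fields, contiguous ecoregions labelled with the standard
#'   terrestrial/freshwater biome vocabularies, Gaussian-niche species with an
#'   analytic occupancy surface, and occurrence samples with injected
#'   contamination matching the four cleaning rules. Everything is
#'   deterministic given a seed.
#' @name synthgen
NULL

#' Bioclimatic variable codes, in canonical table order
#'
#' The nine variables used throughout: annual mean temperature (Bio1, deg C),
#' mean diurnal range (Bio2, deg C), temperature seasonality (Bio4, SD x 100),
#' max temperature of warmest month (Bio5, deg C), min temperature of coldest
#' month (Bio6, deg C), annual precipitation (Bio12, mm), precipitation of
#' wettest/driest month (Bio13/Bio14, mm), precipitation seasonality (Bio15,
#' coefficient of variation).
#' @export
bio_variables <- c("Bio1", "Bio2", "Bio4", "Bio5", "Bio6",
                   "Bio12", "Bio13", "Bio14", "Bio15")

precip_variables <- c("Bio12", "Bio13", "Bio14", "Bio15")

#' Biome code vocabularies
#'
#' Terrestrial and freshwater biome codes as used in global ecoregion maps
#' (e.g. TBMF = temperate broadleaf and mixed forests, XFEB = xeric
#' freshwaters and endorheic basins).
#' @export
terrestrial_biomes <- c("BF", "DXS", "FGS", "IW", "MG", "MFWS", "MGS", "RI",
                        "TBMF", "TCF", "TGSS", "TSCF", "TSDBF", "TSGSS",
                        "TSMBF", "TD")

#' @rdname terrestrial_biomes
#' @export
freshwater_biomes <- c("LL", "LRD", "MF", "OI", "PF", "TCR", "TFRW", "TUR",
                       "TSCR", "TSFRWC", "TSUR", "XFEB")

#' Growth-form vocabulary
#' @export
growth_forms <- c("palm", "succulent", "alga", "fern", "aquatic plant",
                  "vine", "shrub", "tree", "herb")

# --- seeding contract ------------------------------------------------------

# One global seed fans out to per-component child seeds by fixed offsets so a
# module can be re-run in isolation; all seeds stay below 2^31 - 1.
child_seed <- function(seed, offset) {
  s <- (as.numeric(seed) + 9973 * as.numeric(offset)) %% 2147483629
  as.integer(s) + 1L
}

# evaluate `code` under `seed` without clobbering the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# --- random fields ---------------------------------------------------------

# separable Gaussian smoothing with edge renormalisation; `scale` is the
# kernel standard deviation in pixels
smooth_field <- function(mat, scale) {
  if (scale <= 0) stop("'scale' must be positive")
  half <- max(1L, ceiling(3 * scale))
  k <- stats::dnorm(seq(-half, half), sd = scale)
  k <- k / sum(k)
  conv1 <- function(v) {
    n <- length(v)
    out <- stats::convolve(c(rep(0, half), v, rep(0, half)), rev(k),
                           type = "open")
    out[(2 * half + 1):(2 * half + n)]
  }
  num <- apply(mat, 2, conv1)
  num <- t(apply(num, 1, conv1))
  ones <- matrix(1, nrow(mat), ncol(mat))
  den <- apply(ones, 2, conv1)
  den <- t(apply(den, 1, conv1))
  num / den
}

# smoothed standard-normal field rescaled to unit variance
standard_field <- function(n_rows, n_cols, autocorr_scale) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  z <- smooth_field(z, autocorr_scale)
  (z - mean(z)) / stats::sd(z)
}

# --- climate ---------------------------------------------------------------

new_climate_stack <- function(grid, layers, scenario = "current", gcm = NULL) {
  stopifnot(inherits(grid, "grid_spec"), is.list(layers))
  bad <- setdiff(names(layers), bio_variables)
  if (length(bad)) stop("unknown variable code(s): ", paste(bad, collapse = ", "))
  for (nm in names(layers)) {
    if (!identical(dim(layers[[nm]]), c(grid$n_rows, grid$n_cols))) {
      stop("layer '", nm, "' is not co-registered with the grid")
    }
  }
  if (!is.null(grid$nodata_mask)) {
    layers <- lapply(layers, function(m) { m[grid$nodata_mask] <- NA_real_; m })
  }
  structure(list(grid = grid, layers = layers[intersect(bio_variables, names(layers))],
                 scenario = scenario, gcm = gcm),
            class = "climate_stack")
}

#' @export
print.climate_stack <- function(x, ...) {
  cat(sprintf("<climate_stack> %s%s: %d layer(s) [%s] on %dx%d grid\n",
              x$scenario, if (is.null(x$gcm)) "" else paste0("/", x$gcm),
              length(x$layers), paste(names(x$layers), collapse = ","),
              x$grid$n_rows, x$grid$n_cols))
  invisible(x)
}

stack_variables <- function(stack) names(stack$layers)

#' Generate a synthetic bioclimatic stack
#'
#' Each variable is a smoothed Gaussian random field on its own plausible
#' scale; temperature variables additionally carry a gradient of warming
#' toward low absolute latitude, and temperature seasonality (Bio4) increases
#' away from the equator. Precipitation variables are truncated at zero.
#' With `consistent = TRUE` (default) the per-pixel ordering
#' Bio6 <= Bio1 <= Bio5 is enforced by sorting, so the world is physically
#' plausible.
#'
#' @param grid A [grid_spec()].
#' @param seed Integer seed; the same call is bit-reproducible.
#' @param autocorr_scale Gaussian smoothing scale in pixels (> 0).
#' @param consistent Enforce Bio6 <= Bio1 <= Bio5 per pixel.
#' @return A `climate_stack` with the nine canonical layers, scenario
#'   `"current"`.
#' @export
generate_climate <- function(grid, seed, autocorr_scale = 4, consistent = TRUE) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.numeric(autocorr_scale) || autocorr_scale <= 0) {
    stop("'autocorr_scale' must be positive")
  }
  with_seed(child_seed(seed, 1L), {
    nr <- grid$n_rows; nc <- grid$n_cols
    lat <- matrix(abs(row_latitudes(grid)), nr, nc)
    f <- function() standard_field(nr, nc, autocorr_scale)
    bio1 <- 26 - 0.7 * lat + 5 * f()
    bio5 <- bio1 + 8 + 6 * f()
    bio6 <- bio1 - 8 + 6 * f()
    if (consistent) {
      trip <- cbind(as.vector(bio6), as.vector(bio1), as.vector(bio5))
      srt <- t(apply(trip, 1, sort))
      bio6 <- matrix(srt[, 1], nr, nc)
      bio1 <- matrix(srt[, 2], nr, nc)
      bio5 <- matrix(srt[, 3], nr, nc)
    }
    layers <- list(
      Bio1  = bio1,
      Bio2  = 10 + 3 * f(),
      Bio4  = 2000 + 150 * lat + 900 * f(),
      Bio5  = bio5,
      Bio6  = bio6,
      Bio12 = pmax(1100 + 550 * f(), 0),
      Bio13 = pmax(180 + 90 * f(), 0),
      Bio14 = pmax(35 + 30 * f(), 0),
      Bio15 = pmax(55 + 25 * f(), 0))
    new_climate_stack(grid, layers, scenario = "current")
  })
}

# --- scenarios -------------------------------------------------------------

#' Construct a scenario delta
#'
#' A set of additive per-variable shift grids taking a current stack to a
#' future one. Entries may be scalars (applied uniformly) or matrices
#' co-registered with the target grid; variables without an entry are left
#' unchanged.
#'
#' @param deltas Named list (names are Bio codes) of scalars or matrices.
#' @param scenario Label, e.g. `"current"`, `"RCP4.5"`, `"RCP8.5"`.
#' @param gcm Optional climate-model label.
#' @return An object of class `scenario_delta`.
#' @export
scenario_delta <- function(deltas, scenario, gcm = NULL) {
  stopifnot(is.list(deltas))
  bad <- setdiff(names(deltas), bio_variables)
  if (length(bad)) stop("unknown variable code(s): ", paste(bad, collapse = ", "))
  structure(list(deltas = deltas, scenario = scenario, gcm = gcm),
            class = "scenario_delta")
}

#' Generate a synthetic future-scenario delta
#'
#' Emulates a single climate model's late-century anomaly: uniform warming of
#' the temperature variables plus smooth spatial variation, an increase in
#' temperature seasonality, and a smooth zero-mean precipitation anomaly.
#' `scale` multiplies every shift, so a high-forcing pathway can be built as
#' twice a moderate one.
#'
#' @param grid A [grid_spec()].
#' @param seed Integer seed.
#' @param warming Mean temperature increase, deg C (applied to Bio1/Bio5/Bio6).
#' @param seasonality_shift Mean Bio4 increase (SD x 100 units).
#' @param precip_sd Spatial SD of the zero-mean Bio12 anomaly, mm.
#' @param scale Overall multiplier (e.g. 1 for RCP4.5, 2 for RCP8.5).
#' @param spatial_sd SD of the smooth spatial component added to the uniform
#'   temperature shift, deg C.
#' @param autocorr_scale Smoothing scale in pixels for anomaly fields.
#' @param scenario,gcm Labels stored on the delta.
#' @return A [scenario_delta()].
#' @export
generate_scenario_delta <- function(grid, seed, warming = 2.2,
                                    seasonality_shift = 180, precip_sd = 60,
                                    scale = 1, spatial_sd = 0.6,
                                    autocorr_scale = 6,
                                    scenario = "RCP4.5", gcm = NULL) {
  with_seed(child_seed(seed, 2L), {
    nr <- grid$n_rows; nc <- grid$n_cols
    f <- function() standard_field(nr, nc, autocorr_scale)
    dT <- scale * (warming + spatial_sd * f())
    deltas <- list(
      Bio1 = dT,
      Bio4 = scale * (seasonality_shift + 40 * f()),
      Bio5 = dT + scale * 0.3 * f(),
      Bio6 = dT + scale * 0.3 * f(),
      Bio12 = scale * precip_sd * f())
    scenario_delta(deltas, scenario = scenario, gcm = gcm)
  })
}

#' Apply a scenario delta to a climate stack
#'
#' Pure per-pixel addition: `future = current + delta` for every variable
#' with an entry in the delta. The current scenario corresponds to an
#' all-zero delta.
#'
#' @param stack A `climate_stack`.
#' @param delta A [scenario_delta()].
#' @return A new `climate_stack` labelled with the delta's scenario/gcm.
#' @export
apply_scenario <- function(stack, delta) {
  stopifnot(inherits(stack, "climate_stack"), inherits(delta, "scenario_delta"))
  layers <- stack$layers
  for (nm in names(delta$deltas)) {
    if (!nm %in% names(layers)) next
    d <- delta$deltas[[nm]]
    if (is.matrix(d)) {
      if (!identical(dim(d), dim(layers[[nm]]))) {
        stop("delta for '", nm, "' is not co-registered with the stack")
      }
    } else if (length(d) != 1L) {
      stop("delta for '", nm, "' must be a scalar or a matrix")
    }
    layers[[nm]] <- layers[[nm]] + d
  }
  new_climate_stack(stack$grid, layers, scenario = delta$scenario,
                    gcm = delta$gcm)
}

# --- ecoregions ------------------------------------------------------------

new_ecoregion_map <- function(grid, labels, meta) {
  stopifnot(inherits(grid, "grid_spec"),
            identical(dim(labels), c(grid$n_rows, grid$n_cols)),
            all(c("ecoregion_id", "name", "biome", "realm") %in% names(meta)))
  structure(list(grid = grid, labels = labels, meta = meta),
            class = "ecoregion_map")
}

#' @export
print.ecoregion_map <- function(x, ...) {
  cat(sprintf("<ecoregion_map> %d ecoregions, %d biome(s), realm(s): %s\n",
              nrow(x$meta), length(unique(x$meta$biome)),
              paste(unique(x$meta$realm), collapse = ",")))
  invisible(x)
}

#' Generate contiguous synthetic ecoregions
#'
#' Multi-source breadth-first region growing from `n_regions` seed pixels
#' sampled uniformly over usable pixels: every non-nodata pixel receives the
#' label of the geodesically nearest seed, which guarantees contiguity under
#' 4-adjacency. Each region carries one biome code (sampled from
#' `biome_table`) and one realm.
#'
#' @param grid A [grid_spec()].
#' @param n_regions Number of ecoregions (1 <= n_regions <= usable pixels).
#' @param biome_table Character vector of biome codes, drawn from
#'   [terrestrial_biomes] and/or [freshwater_biomes].
#' @param seed Integer seed.
#' @param realm Realm label; by default inferred from the biome codes.
#' @return An `ecoregion_map` with integer `labels` matrix (NA on nodata) and
#'   a `meta` data.frame (ecoregion_id, name, biome, realm).
#' @export
generate_ecoregions <- function(grid, n_regions, biome_table, seed,
                                realm = NULL) {
  stopifnot(inherits(grid, "grid_spec"), n_regions >= 1)
  known <- c(terrestrial_biomes, freshwater_biomes)
  bad <- setdiff(biome_table, known)
  if (length(bad)) stop("unknown biome code(s): ", paste(bad, collapse = ", "))
  if (is.null(realm)) {
    realm <- if (all(biome_table %in% terrestrial_biomes)) "terrestrial"
             else if (all(biome_table %in% freshwater_biomes)) "freshwater"
             else "mixed"
  }
  ok <- usable_mask(grid)
  usable <- which(ok)
  if (n_regions > length(usable)) {
    stop("n_regions exceeds the number of usable pixels")
  }
  with_seed(child_seed(seed, 3L), {
    seeds <- sample(usable, n_regions)
    labels <- matrix(NA_integer_, grid$n_rows, grid$n_cols)
    labels[seeds] <- seq_len(n_regions)
    # multi-source BFS, FIFO over pixels; first arrival wins => contiguous
    nr <- grid$n_rows
    queue <- seeds
    head <- 1L
    while (head <= length(queue)) {
      p <- queue[head]; head <- head + 1L
      lab <- labels[p]
      r <- ((p - 1L) %% nr) + 1L
      cc <- ((p - 1L) %/% nr) + 1L
      for (q in c(if (r > 1L) p - 1L, if (r < nr) p + 1L,
                  if (cc > 1L) p - nr, if (cc < grid$n_cols) p + nr)) {
        if (ok[q] && is.na(labels[q])) {
          labels[q] <- lab
          queue[length(queue) + 1L] <- q
        }
      }
    }
    biomes <- sample(biome_table, n_regions, replace = TRUE)
    meta <- data.frame(ecoregion_id = seq_len(n_regions),
                       name = sprintf("ER%03d", seq_len(n_regions)),
                       biome = biomes, realm = realm,
                       stringsAsFactors = FALSE)
    new_ecoregion_map(grid, labels, meta)
  })
}

# --- species ---------------------------------------------------------------

#' Define a species' climatic niche
#'
#' Occupancy probability is a product of independent per-variable Gaussian
#' kernels scaled by `max_prob`:
#' `p(x) = max_prob * prod_v exp(-(x_v - opt_v)^2 / (2 * breadth_v^2))`,
#' hence in `[0, 1]` everywhere. Variables absent from `optimum` do not
#' constrain the species.
#'
#' @param species_id Species name (binomial-style, e.g. `"Invadia prima"`).
#' @param growth_form One of [growth_forms].
#' @param optimum Named numeric vector of niche optima (names are Bio codes).
#' @param breadth Named positive numeric vector, same names as `optimum`.
#' @param max_prob Peak occupancy probability in (0, 1].
#' @return An object of class `niche_spec`.
#' @export
niche_spec <- function(species_id, growth_form, optimum, breadth,
                       max_prob = 0.9) {
  stopifnot(is.character(species_id), length(species_id) == 1L)
  if (!growth_form %in% growth_forms) {
    stop("unknown growth form: ", growth_form)
  }
  stopifnot(is.numeric(optimum), is.numeric(breadth),
            identical(sort(names(optimum)), sort(names(breadth))),
            all(names(optimum) %in% bio_variables),
            all(breadth > 0), max_prob > 0, max_prob <= 1)
  structure(list(species_id = species_id, growth_form = growth_form,
                 optimum = optimum, breadth = breadth[names(optimum)],
                 max_prob = max_prob),
            class = "niche_spec")
}

#' True occupancy surface of a synthetic species
#'
#' @param niche A [niche_spec()].
#' @param stack A `climate_stack` containing every niche variable.
#' @return Matrix of occupancy probabilities in `[0, 1]` (NA on nodata).
#' @export
true_occupancy <- function(niche, stack) {
  stopifnot(inherits(niche, "niche_spec"), inherits(stack, "climate_stack"))
  miss <- setdiff(names(niche$optimum), stack_variables(stack))
  if (length(miss)) stop("stack lacks niche variable(s): ",
                         paste(miss, collapse = ", "))
  occ <- matrix(niche$max_prob, stack$grid$n_rows, stack$grid$n_cols)
  for (v in names(niche$optimum)) {
    z <- (stack$layers[[v]] - niche$optimum[[v]]) / niche$breadth[[v]]
    occ <- occ * exp(-0.5 * z^2)
  }
  occ
}

#' Generate a pool of synthetic species
#'
#' Niche optima are placed at random quantiles (between `q_range[1]` and
#' `q_range[2]`) of the realised current climate, so every species has
#' habitat on the map; breadths are `breadth_frac` times the landscape SD of
#' each driver variable. Growth forms cycle through the standard vocabulary.
#'
#' @param n_species Number of species.
#' @param stack Current-scenario `climate_stack`.
#' @param seed Integer seed.
#' @param driver_vars Bio codes the niches depend on.
#' @param breadth_frac Niche breadth as a fraction of each variable's SD.
#' @param q_range Quantile window for optimum placement.
#' @param max_prob Peak occupancy.
#' @return List of [niche_spec()] objects.
#' @export
synth_species <- function(n_species, stack, seed,
                          driver_vars = c("Bio1", "Bio4", "Bio12"),
                          breadth_frac = 0.1, q_range = c(0.25, 0.75),
                          max_prob = 0.9) {
  stopifnot(all(driver_vars %in% stack_variables(stack)))
  with_seed(child_seed(seed, 4L), {
    lapply(seq_len(n_species), function(i) {
      opt <- vapply(driver_vars, function(v) {
        x <- stack$layers[[v]]
        stats::quantile(x[!is.na(x)], stats::runif(1, q_range[1], q_range[2]),
                        names = FALSE)
      }, numeric(1))
      br <- vapply(driver_vars, function(v) {
        breadth_frac * stats::sd(stack$layers[[v]], na.rm = TRUE)
      }, numeric(1))
      # letter-only epithets so the names pass the binomial-name predicate
      niche_spec(sprintf("Invadia %s",
                         strrep(letters[((i - 1L) %% 26L) + 1L],
                                ((i - 1L) %/% 26L) + 2L)),
                 growth_forms[((i - 1L) %% length(growth_forms)) + 1L],
                 optimum = opt, breadth = br, max_prob = max_prob)
    })
  })
}

# --- occurrences -----------------------------------------------------------

#' Sample contaminated occurrence records for a synthetic species
#'
#' Clean records occupy `n_clean` distinct grid cells drawn without
#' replacement with probability proportional to the true occupancy surface;
#' coordinates are jittered uniformly within the cell. Contaminant records
#' are appended afterwards and flagged in the hidden ground-truth column
#' `truth`: extra records duplicating already-sampled cells
#' (`cell_duplicate`), records at exactly (0, 0) (`zero_zero`), records with
#' longitude equal to latitude (`lon_eq_lat`), and records whose `name_raw`
#' fails the binomial-name predicate (`bad_name`).
#'
#' @param niche A [niche_spec()].
#' @param stack Current `climate_stack`.
#' @param n_clean Number of clean records (distinct cells), >= 1.
#' @param contamination List with integer entries `n_cell_duplicates`,
#'   `n_zero_zero`, `n_lon_eq_lat`, `n_bad_names` (all default 0).
#' @param seed Integer seed.
#' @param distinct_cells With the default `TRUE`, clean records occupy
#'   distinct cells (so the per-rule removal counts of the cleaning stage
#'   equal the injected contamination exactly, and the post-cleaning record
#'   count is `n_clean`). With `FALSE`, cells are drawn with replacement —
#'   the literal "proportional to occupancy" sampling law, emulating raw
#'   aggregator data with many records per cell.
#' @return A data.frame with columns `species`, `growth_form`, `lon`, `lat`,
#'   `name_raw`, `truth` (`"clean"` or the contaminant class).
#' @export
sample_occurrences <- function(niche, stack, n_clean,
                               contamination = list(), seed = 1L,
                               distinct_cells = TRUE) {
  stopifnot(inherits(niche, "niche_spec"), inherits(stack, "climate_stack"),
            n_clean >= 1)
  con <- utils::modifyList(
    list(n_cell_duplicates = 0L, n_zero_zero = 0L,
         n_lon_eq_lat = 0L, n_bad_names = 0L), as.list(contamination))
  for (v in names(niche$optimum)) {
    x <- stack$layers[[v]]
    if (niche$optimum[[v]] < min(x, na.rm = TRUE) ||
        niche$optimum[[v]] > max(x, na.rm = TRUE)) {
      warning("niche optimum for ", v,
              " lies outside the climate range; species will be rare")
    }
  }
  occ <- true_occupancy(niche, stack)
  grid <- stack$grid
  eligible <- which(!is.na(occ) & occ > 0 & usable_mask(grid))
  if (distinct_cells && length(eligible) < n_clean) {
    stop("fewer than n_clean cells with positive occupancy")
  }
  with_seed(child_seed(seed, 5L), {
    cells <- sample(eligible, n_clean, replace = !distinct_cells,
                    prob = occ[eligible])
    jitter_in_cell <- function(cells) {
      r <- ((cells - 1L) %% grid$n_rows) + 1L
      cc <- ((cells - 1L) %/% grid$n_rows) + 1L
      data.frame(
        lon = grid$origin_lon + (cc - 1 + stats::runif(length(cells))) *
          grid$cell_size,
        lat = grid$origin_lat + (r - 1 + stats::runif(length(cells))) *
          grid$cell_size)
    }
    rec <- function(xy, name_raw, truth) {
      if (nrow(xy) == 0) return(NULL)
      data.frame(species = niche$species_id, growth_form = niche$growth_form,
                 lon = xy$lon, lat = xy$lat, name_raw = name_raw,
                 truth = truth, stringsAsFactors = FALSE)
    }
    out <- list(rec(jitter_in_cell(cells), niche$species_id, "clean"))
    if (con$n_cell_duplicates > 0) {
      dup <- cells[((seq_len(con$n_cell_duplicates) - 1L) %% n_clean) + 1L]
      out <- c(out, list(rec(jitter_in_cell(dup), niche$species_id,
                             "cell_duplicate")))
    }
    if (con$n_zero_zero > 0) {
      xy <- data.frame(lon = rep(0, con$n_zero_zero),
                       lat = rep(0, con$n_zero_zero))
      out <- c(out, list(rec(xy, niche$species_id, "zero_zero")))
    }
    if (con$n_lon_eq_lat > 0) {
      v <- stats::runif(con$n_lon_eq_lat, 5, 60) *
        sample(c(-1, 1), con$n_lon_eq_lat, replace = TRUE)
      out <- c(out, list(rec(data.frame(lon = v, lat = v), niche$species_id,
                             "lon_eq_lat")))
    }
    if (con$n_bad_names > 0) {
      bad_cells <- sample(eligible, con$n_bad_names)
      out <- c(out, list(rec(jitter_in_cell(bad_cells),
                             sprintf("%s sp. %d!!", niche$species_id,
                                     seq_len(con$n_bad_names)),
                             "bad_name")))
    }
    do.call(rbind, out)
  })
}
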