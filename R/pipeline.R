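#' @title End-to-end pipeline
#' @description One-call orchestration of the whole analysis on a synthetic
#'   world: climate + ecoregion + species generation, occurrence QC,
#'   collinearity screening, per-species cross-validated suitability
#'   modelling, evaluation/retention, expansion-potential aggregation per
#'   scenario (and per growth form), the cross-scenario regression, and the
#'   climate-feature attribution stage. Everything is driven by a single
#'   config list and is deterministic given `config$seed`.
#' @name pipeline_cli
NULL

#' Default pipeline configuration
#'
#' Modelling defaults are the canonical settings: regularisation multiplier
#' 1.5, 10-fold cross-validation, up to 10,000 background points, AUC
#' retention bound 0.7, mean-omission bound 0.017, collinearity threshold
#' 0.85. [demo_config()] shrinks the world and the modelling effort so the
#' full pipeline runs in seconds.
#'
#' @return A nested config list (see the vignette for the schema).
#' @export
default_config <- function() {
  list(
    seed = 1L,
    grid = list(n_rows = 60L, n_cols = 90L, cell_size = 1 / 6,
                origin_lon = 0, origin_lat = 0),
    synth = list(autocorr_scale = 4, n_species = 6L,
                 driver_vars = c("Bio1", "Bio4", "Bio12"),
                 breadth_frac = 0.1, max_prob = 0.9, n_clean = 300L,
                 contamination = list(n_cell_duplicates = 5L,
                                      n_zero_zero = 3L, n_lon_eq_lat = 3L,
                                      n_bad_names = 4L),
                 n_regions_terrestrial = 12L, n_regions_freshwater = 8L,
                 gcms = c("gcmA", "gcmB", "gcmC", "gcmD"),
                 warming = 2.2, seasonality_shift = 180, rcp85_scale = 2),
    qc = list(min_records = 100L, strict = TRUE),
    climate = list(collinearity_threshold = 0.85, sample_pixels = Inf),
    sdm = list(beta = 1.5, k = 10L, n_background = 10000L, n_knots = 20L,
               bias_bandwidth = Inf, tol = 1e-4, max_iter = 3000L),
    retention = list(auc_min = 0.7, omission_max = 0.017),
    features = list(top_k = 2L, with_only = TRUE),
    out_dir = NULL)
}

#' @rdname default_config
#' @export
demo_config <- function() {
  cfg <- default_config()
  cfg$grid$n_rows <- 48L
  cfg$grid$n_cols <- 72L
  cfg$synth$n_species <- 4L
  cfg$synth$n_clean <- 150L
  cfg$synth$gcms <- c("gcmA", "gcmB")
  cfg$sdm$k <- 3L
  cfg$sdm$n_knots <- 8L
  cfg$sdm$n_background <- 2000L
  cfg
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run the full pipeline
#'
#' @param config A config list; missing entries fall back to
#'   [demo_config()]. Pass [default_config()] (or overrides of it) for the
#'   canonical settings.
#' @return (Invisibly) a list bundle: the synthetic world, QC output,
#'   screening report, per-species models and evaluations, suitability /
#'   change maps, expansion tables (per scenario, realm, biome and growth
#'   form), the cross-scenario regression, the attribution outputs, and a
#'   machine-readable `manifest`. If `config$out_dir` is set, all tables
#'   plus the manifest are written there as CSV/JSON.
#' @export
run_pipeline <- function(config = demo_config()) {
  cfg <- merge_config(demo_config(), config)
  seed <- cfg$seed
  g <- cfg$grid
  grid <- grid_spec(g$n_rows, g$n_cols, g$cell_size, g$origin_lon,
                    g$origin_lat)

  ## synthetic world ---------------------------------------------------
  current <- generate_climate(grid, seed, cfg$synth$autocorr_scale)
  scen_scale <- c("RCP4.5" = 1, "RCP8.5" = cfg$synth$rcp85_scale)
  futures <- lapply(names(scen_scale), function(sc) {
    members <- lapply(seq_along(cfg$synth$gcms), function(i) {
      d <- generate_scenario_delta(
        grid, child_seed(seed, 10L + i), warming = cfg$synth$warming,
        seasonality_shift = cfg$synth$seasonality_shift,
        scale = scen_scale[[sc]], scenario = sc, gcm = cfg$synth$gcms[i])
      apply_scenario(current, d)
    })
    ensemble_mean(members)
  })
  names(futures) <- names(scen_scale)

  regions <- list(
    terrestrial = generate_ecoregions(grid,
                                      cfg$synth$n_regions_terrestrial,
                                      terrestrial_biomes,
                                      child_seed(seed, 20L)),
    freshwater = generate_ecoregions(grid, cfg$synth$n_regions_freshwater,
                                     freshwater_biomes,
                                     child_seed(seed, 21L)))

  niches <- synth_species(cfg$synth$n_species, current, seed,
                          driver_vars = cfg$synth$driver_vars,
                          breadth_frac = cfg$synth$breadth_frac,
                          max_prob = cfg$synth$max_prob)
  occ_raw <- do.call(rbind, lapply(seq_along(niches), function(i) {
    sample_occurrences(niches[[i]], current, cfg$synth$n_clean,
                       contamination = cfg$synth$contamination,
                       seed = child_seed(seed, 100L + i))
  }))

  ## QC ------------------------------------------------------------------
  qc <- clean_occurrences(occ_raw, grid)
  flt <- filter_species(qc$table, min_records = cfg$qc$min_records,
                        strict = cfg$qc$strict)
  occ <- flt$table

  ## climate screening ----------------------------------------------------
  screen <- screen_collinearity(current,
                                sample_pixels = cfg$climate$sample_pixels,
                                threshold = cfg$climate$collinearity_threshold,
                                seed = seed)
  cur_s <- subset_stack(current, screen$retained)
  fut_s <- lapply(futures, subset_stack, vars = screen$retained)

  ## per-species modelling ------------------------------------------------
  species <- intersect(vapply(niches, `[[`, character(1), "species_id"),
                       unique(occ$species))
  sdm_cfg <- cfg$sdm
  fits <- list()
  for (i in seq_along(species)) {
    sp <- species[i]
    sp_occ <- occ[occ$species == sp, , drop = FALSE]
    cv <- cross_validate(sp_occ, cur_s, k = sdm_cfg$k,
                         seed = child_seed(seed, 200L + i),
                         beta = sdm_cfg$beta, n_knots = sdm_cfg$n_knots,
                         tol = sdm_cfg$tol, max_iter = sdm_cfg$max_iter,
                         n_background = sdm_cfg$n_background,
                         bias_bandwidth = sdm_cfg$bias_bandwidth)
    ev <- evaluate_sdm(cv, auc_min = cfg$retention$auc_min,
                       omission_max = cfg$retention$omission_max)
    fut_maps <- lapply(fut_s, function(st) project_cv(cv, st))
    fits[[sp]] <- list(species = sp,
                       growth_form = sp_occ$growth_form[1L], cv = cv,
                       evaluation = ev, current_map = cv$mean_map,
                       future_maps = fut_maps)
  }
  retained_sp <- names(fits)[vapply(fits, function(f) f$evaluation$retained,
                                    logical(1))]
  if (!length(retained_sp)) stop("no species passed the retention rule")

  ## expansion ------------------------------------------------------------
  maps_of <- function(sp_set, what, scenario = NULL) {
    lapply(fits[sp_set], function(f) {
      if (what == "current") f$current_map else f$future_maps[[scenario]]
    })
  }
  expansion <- list()
  potentials_by_scenario <- list()
  e_cur <- multi_species_suitability(maps_of(retained_sp, "current"))
  for (sc in names(futures)) {
    e_fut <- multi_species_suitability(maps_of(retained_sp, "future", sc))
    a <- suitability_change(e_fut, e_cur)
    per_realm <- lapply(regions, function(rg) {
      ecoregion_potential(a, rg, scenario = sc)
    })
    pot <- do.call(rbind, per_realm)
    rownames(pot) <- NULL
    forms <- unique(vapply(fits[retained_sp], `[[`, character(1),
                           "growth_form"))
    by_form <- do.call(rbind, lapply(forms, function(fm) {
      sp_f <- retained_sp[vapply(fits[retained_sp], `[[`, character(1),
                                 "growth_form") == fm]
      ef <- multi_species_suitability(maps_of(sp_f, "future", sc))
      ec <- multi_species_suitability(maps_of(sp_f, "current"))
      af <- ef - ec  # same species subset on both sides
      tb <- do.call(rbind, lapply(regions, ecoregion_potential,
                                  change = af, scenario = sc))
      tb$growth_form <- fm
      tb
    }))
    rownames(by_form) <- NULL
    expansion[[sc]] <- list(change_map = a, potentials = pot,
                            by_biome = group_potentials(pot, "biome"),
                            by_growth_form = group_potentials(by_form,
                                                              "growth_form"),
                            potentials_by_form = by_form)
    potentials_by_scenario[[sc]] <- pot
  }
  rcp_reg <- scenario_regression(
    potentials_by_scenario[["RCP4.5"]]$potential,
    potentials_by_scenario[["RCP8.5"]]$potential)

  ## climate features -----------------------------------------------------
  importances <- lapply(fits[retained_sp], function(f) {
    jackknife_importance(f$cv$presence_values, f$cv$background_values,
                         beta = sdm_cfg$beta, n_knots = sdm_cfg$n_knots,
                         tol = sdm_cfg$tol, max_iter = sdm_cfg$max_iter,
                         with_only = cfg$features$with_only)
  })
  imp_mean <- mean_importance(importances)
  top_vars <- select_top_variables(imp_mean, k = cfg$features$top_k)
  cv_tables <- list()
  feature_regressions <- list()
  for (v in top_vars) {
    for (sc in names(futures)) {
      for (realm in names(regions)) {
        cvt <- variable_change(current, futures[[sc]], regions[[realm]], v)
        key <- paste(v, sc, realm, sep = ".")
        cv_tables[[key]] <- cvt
        pots <- potentials_by_scenario[[sc]]
        reg <- potential_vs_change_regression(
          pots[pots$realm == realm, ], cvt)
        reg$variable <- v; reg$scenario <- sc; reg$realm <- realm
        feature_regressions[[key]] <- reg
      }
    }
  }
  feature_regressions <- do.call(rbind, feature_regressions)
  rownames(feature_regressions) <- NULL
  change_summaries <- do.call(rbind, lapply(top_vars, function(v) {
    do.call(rbind, lapply(names(regions), function(realm) {
      s <- biome_change_summary(
        cv_tables[[paste(v, "RCP4.5", realm, sep = ".")]],
        potentials_by_scenario[["RCP4.5"]][
          potentials_by_scenario[["RCP4.5"]]$realm == realm, ])
      if (nrow(s)) { s$variable <- v; s$realm <- realm }
      s
    }))
  }))
  rownames(change_summaries) <- NULL

  ## bundle + manifest ----------------------------------------------------
  eval_summary <- do.call(rbind, lapply(fits, function(f) {
    data.frame(species = f$species, growth_form = f$growth_form,
               mean_auc = f$evaluation$mean_auc,
               mean_omission = f$evaluation$mean_omission,
               retained = f$evaluation$retained, stringsAsFactors = FALSE)
  }))
  rownames(eval_summary) <- NULL
  bundle <- list(config = cfg, grid = grid, current = current,
                 futures = futures, regions = regions, niches = niches,
                 occurrences_raw = occ_raw, qc = qc, species_filter = flt,
                 screen = screen, fits = fits,
                 retained_species = retained_sp,
                 evaluation_summary = eval_summary, expansion = expansion,
                 scenario_regression = rcp_reg, importances = importances,
                 importance_mean = imp_mean, top_variables = top_vars,
                 variable_changes = cv_tables,
                 feature_regressions = feature_regressions,
                 change_summaries = change_summaries)
  bundle$manifest <- build_manifest(bundle)
  if (!is.null(cfg$out_dir)) write_bundle(bundle, cfg$out_dir)
  invisible(bundle)
}

build_manifest <- function(bundle) {
  list(package_version = as.character(utils::packageVersion("ipsexp")),
       seed = bundle$config$seed,
       n_species_configured = bundle$config$synth$n_species,
       n_records_raw = nrow(bundle$occurrences_raw),
       n_records_clean = nrow(bundle$qc$table),
       qc_removed = as.list(bundle$qc$report$removed),
       variables_retained = bundle$screen$retained,
       species_retained = bundle$retained_species,
       top_variables = bundle$top_variables,
       scenario_regression = bundle$scenario_regression,
       potential_checksum = vapply(bundle$expansion, function(e) {
         sum(e$potentials$potential, na.rm = TRUE)
       }, numeric(1)))
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  write_grid_json(bundle$grid, fp("grid.json"))
  write_occurrences_csv(bundle$qc$table, fp("occurrences_clean.csv"))
  data.table::fwrite(data.frame(rule = names(bundle$qc$report$removed),
                                removed = bundle$qc$report$removed),
                     fp("qc_report.csv"))
  data.table::fwrite(bundle$screen$dropped, fp("variables_dropped.csv"))
  data.table::fwrite(bundle$evaluation_summary, fp("evaluation.csv"))
  for (sc in names(bundle$expansion)) {
    tag <- gsub("[^A-Za-z0-9]", "", sc)
    data.table::fwrite(bundle$expansion[[sc]]$potentials,
                       fp(sprintf("potentials_%s.csv", tag)))
    data.table::fwrite(bundle$expansion[[sc]]$by_biome,
                       fp(sprintf("potentials_by_biome_%s.csv", tag)))
    data.table::fwrite(bundle$expansion[[sc]]$by_growth_form,
                       fp(sprintf("potentials_by_growth_form_%s.csv", tag)))
  }
  imp <- do.call(rbind, lapply(names(bundle$importances), function(sp) {
    x <- bundle$importances[[sp]]; x$species <- sp; x
  }))
  data.table::fwrite(imp, fp("importance.csv"))
  data.table::fwrite(bundle$feature_regressions,
                     fp("feature_regressions.csv"))
  data.table::fwrite(bundle$change_summaries, fp("change_summaries.csv"))
  manifest <- bundle$manifest
  files <- list.files(out_dir, pattern = "\\.csv$|\\.json$",
                      full.names = TRUE)
  files <- setdiff(files, fp("manifest.json"))
  manifest$files <- lapply(stats::setNames(files, basename(files)),
                           function(f) unname(tools::md5sum(f)))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(out_dir)
}
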