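test_that("generate_climate produces the nine co-registered layers with the stated structure", {
  grid <- grid_spec(40, 60)
  st <- generate_climate(grid, seed = 7)
  expect_s3_class(st, "climate_stack")
  expect_identical(names(st$layers), bio_variables)
  for (v in names(st$layers)) {
    expect_identical(dim(st$layers[[v]]), c(40L, 60L))
  }
  # precipitation nonnegative by construction
  for (v in c("Bio12", "Bio13", "Bio14", "Bio15")) {
    expect_true(all(st$layers[[v]] >= 0))
  }
  # physically consistent ordering of the temperature triple
  expect_true(all(st$layers$Bio6 <= st$layers$Bio1))
  expect_true(all(st$layers$Bio1 <= st$layers$Bio5))
  # warmer toward low latitudes
  lat <- matrix(rep(grid$origin_lat + (seq_len(40) - 0.5) * grid$cell_size,
                    60), 40, 60)
  expect_lt(stats::cor(as.vector(st$layers$Bio1), as.vector(lat)), 0)
  # fixed-seed determinism, bit identical
  expect_identical(st, generate_climate(grid, seed = 7))
  expect_false(identical(st$layers$Bio1,
                         generate_climate(grid, seed = 8)$layers$Bio1))
  expect_error(generate_climate(grid, 7, autocorr_scale = 0), "positive")
})

test_that("apply_scenario is additive, sequential-composable, and rejects mismatches", {
  grid <- grid_spec(15, 20)
  st <- generate_climate(grid, seed = 3)
  zero <- scenario_delta(list(Bio1 = 0), scenario = "current")
  expect_equal(apply_scenario(st, zero)$layers, st$layers)
  plus2 <- scenario_delta(list(Bio1 = 2.0), scenario = "RCP4.5")
  fut <- apply_scenario(st, plus2)
  expect_identical(fut$layers$Bio1, st$layers$Bio1 + 2.0)
  expect_identical(fut$layers$Bio12, st$layers$Bio12)
  expect_identical(fut$scenario, "RCP4.5")
  # two deltas applied sequentially equal one summed delta
  d1 <- generate_scenario_delta(grid, 5, scenario = "RCP4.5")
  d2 <- generate_scenario_delta(grid, 9, scenario = "RCP4.5")
  seqd <- apply_scenario(apply_scenario(st, d1), d2)
  summed <- scenario_delta(Map(`+`, d1$deltas, d2$deltas[names(d1$deltas)]),
                           scenario = "RCP4.5")
  expect_equal(seqd$layers, apply_scenario(st, summed)$layers,
               tolerance = 1e-12)
  bad <- scenario_delta(list(Bio1 = matrix(1, 3, 3)), scenario = "x")
  expect_error(apply_scenario(st, bad), "co-registered")
})

test_that("scenario application commutes with ensembling", {
  grid <- grid_spec(12, 18)
  st <- generate_climate(grid, seed = 2)
  deltas <- lapply(1:4, function(i) {
    generate_scenario_delta(grid, 100 + i, scenario = "RCP4.5",
                            gcm = paste0("g", i))
  })
  ens <- ensemble_mean(lapply(deltas, apply_scenario, stack = st))
  mean_delta <- scenario_delta(
    lapply(stats::setNames(nm = names(deltas[[1]]$deltas)), function(v) {
      Reduce(`+`, lapply(deltas, function(d) d$deltas[[v]])) / 4
    }), scenario = "RCP4.5")
  direct <- apply_scenario(st, mean_delta)
  for (v in bio_variables) {
    expect_equal(ens$layers[[v]], direct$layers[[v]], tolerance = 1e-12)
  }
})

test_that("generate_ecoregions partitions the grid into contiguous labelled regions", {
  grid <- grid_spec(40, 60)
  one <- generate_ecoregions(grid, 1, "TBMF", seed = 1)
  expect_true(all(one$labels == 1L))

  em <- generate_ecoregions(grid, 12, terrestrial_biomes, seed = 3)
  # partition: per-region counts sum to the pixel count, no NA labels
  expect_false(anyNA(em$labels))
  expect_identical(sum(table(em$labels)), 40L * 60L)
  expect_setequal(unique(as.vector(em$labels)), 1:12)
  expect_true(all(em$meta$biome %in% terrestrial_biomes))
  expect_identical(em$meta$realm, rep("terrestrial", 12))
  # contiguity: flood fill from one member pixel recovers each whole region
  flood <- function(labels, id) {
    mask <- labels == id
    seen <- matrix(FALSE, nrow(labels), ncol(labels))
    start <- which(mask)[1L]
    stack_ <- start
    seen[start] <- TRUE
    nr <- nrow(labels)
    while (length(stack_)) {
      p <- stack_[length(stack_)]
      stack_ <- stack_[-length(stack_)]
      r <- ((p - 1) %% nr) + 1
      cc <- ((p - 1) %/% nr) + 1
      for (q in c(if (r > 1) p - 1, if (r < nr) p + 1,
                  if (cc > 1) p - nr, if (cc < ncol(labels)) p + nr)) {
        if (mask[q] && !seen[q]) {
          seen[q] <- TRUE
          stack_ <- c(stack_, q)
        }
      }
    }
    sum(seen) == sum(mask)
  }
  for (id in 1:12) expect_true(flood(em$labels, id))
  expect_identical(em, generate_ecoregions(grid, 12, terrestrial_biomes,
                                           seed = 3))
  expect_error(generate_ecoregions(grid, 40 * 60 + 1, "TBMF", seed = 1),
               "exceeds")
  expect_error(generate_ecoregions(grid, 3, c("TBMF", "NOPE"), seed = 1),
               "unknown biome")
})

test_that("sample_occurrences places clean records on occupied cells and injects exact contamination", {
  w <- small_world(seed = 5)
  niche <- w$niches[[1]]
  occ0 <- sample_occurrences(niche, w$current, n_clean = 80, seed = 2)
  expect_identical(unique(occ0$truth), "clean")
  surf <- true_occupancy(niche, w$current)
  idx <- cell_index(w$grid, occ0$lon, occ0$lat)
  vals <- surf[cbind(idx$row, idx$col)]
  expect_true(all(vals > 0))
  # clean cells are distinct at the working resolution
  expect_identical(anyDuplicated(paste(idx$row, idx$col)), 0L)
  # weighted sampling concentrates on high-occupancy cells
  expect_gt(mean(vals), mean(surf))

  con <- list(n_cell_duplicates = 4, n_zero_zero = 3, n_lon_eq_lat = 2,
              n_bad_names = 5)
  occ <- sample_occurrences(niche, w$current, n_clean = 80,
                            contamination = con, seed = 2)
  expect_identical(nrow(occ), 80L + 4L + 3L + 2L + 5L)
  expect_identical(sum(occ$truth == "zero_zero"), 3L)
  expect_true(all(occ$lon[occ$truth == "zero_zero"] == 0 &
                    occ$lat[occ$truth == "zero_zero"] == 0))
  expect_true(all(occ$lon[occ$truth == "lon_eq_lat"] ==
                    occ$lat[occ$truth == "lon_eq_lat"]))
  expect_true(all(!valid_species_name(occ$name_raw[occ$truth == "bad_name"])))
  expect_identical(occ, sample_occurrences(niche, w$current, n_clean = 80,
                                           contamination = con, seed = 2))
})

test_that("with-replacement clean records follow the occupancy law (chi-square GOF, n = 5000)", {
  grid <- grid_spec(60, 90)
  st <- generate_climate(grid, seed = 21)
  niche <- synth_species(1, st, 21, breadth_frac = 0.6)[[1]]
  occ <- sample_occurrences(niche, st, n_clean = 5000, seed = 4,
                            distinct_cells = FALSE)
  surf <- true_occupancy(niche, st)
  idx <- cell_index(grid, occ$lon, occ$lat)
  # coarse 6x6-pixel bins
  bin <- paste((idx$row - 1) %/% 6, (idx$col - 1) %/% 6)
  rows <- rep(seq_len(60), 90); cols <- rep(seq_len(90), each = 60)
  bin_all <- paste((rows - 1) %/% 6, (cols - 1) %/% 6)
  expected_mass <- tapply(as.vector(surf), bin_all, sum)
  obs <- table(factor(bin, levels = names(expected_mass)))
  p <- expected_mass / sum(expected_mass)
  keep <- p > 1e-8  # chisq.test rejects zero-probability classes
  gof <- suppressWarnings(
    stats::chisq.test(as.vector(obs[keep]), p = p[keep] / sum(p[keep])))
  expect_gt(gof$p.value, 0.01)
})

test_that("a niche optimum outside the climate range warns but still samples", {
  w <- small_world(seed = 8)
  niche <- w$niches[[1]]
  niche$optimum[["Bio1"]] <- max(w$current$layers$Bio1) + 10
  expect_warning(occ <- sample_occurrences(niche, w$current, n_clean = 10,
                                           seed = 1),
                 "outside the climate range")
  expect_identical(nrow(occ), 10L)
})
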