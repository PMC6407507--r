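# climate values for one species in a world driven by known variables
species_data <- function(seed, driver_vars, nr = 30, nc = 45,
                         n_clean = 120, n_bg = 600, breadth_frac = 0.15) {
  w <- small_world(seed = seed, nr = nr, nc = nc,
                   driver_vars = driver_vars, breadth_frac = breadth_frac)
  occ <- sample_occurrences(w$niches[[1]], w$current, n_clean = n_clean,
                            seed = seed + 1)
  bg <- sample_background(occ, w$grid, n_max = n_bg, seed = seed + 2)
  list(pv = extract_values(occ, w$current),
       bv = extract_values(bg, w$current), world = w)
}

test_that("jackknife importance finds a single driving variable and sums to 100", {
  d <- species_data(seed = 71, driver_vars = "Bio12")
  imp <- jackknife_importance(d$pv, d$bv, n_knots = 6)
  expect_s3_class(imp, "variable_importance")
  expect_equal(sum(imp$percent), 100, tolerance = 1e-6)
  expect_true(all(imp$gain_drop >= 0))
  expect_gt(imp$percent[imp$variable == "Bio12"], 90)
  # with-only gain is highest for the driver as well
  expect_identical(imp$variable[which.max(imp$gain_only)], "Bio12")
})

test_that("two exchangeable duplicate drivers share the importance", {
  set.seed(72)
  n <- 500
  x <- runif(n, 0, 10)
  # Bio13 is an exact affine copy of Bio12: symmetric by construction
  bv <- cbind(Bio12 = x, Bio13 = 2 * x + 5)
  q <- exp(-(x - 7)^2 / 2)
  idx <- sample(n, 200, replace = TRUE, prob = q)
  pv <- bv[idx, ]
  imp <- jackknife_importance(pv, bv, n_knots = 8)
  # removing either variable leaves its twin: both drops are (near) zero,
  # and the contributions fall back to the equal split
  expect_equal(imp$percent[1], imp$percent[2], tolerance = 10)
  expect_equal(sum(imp$percent), 100, tolerance = 1e-6)
})

test_that("jackknife importance is invariant to affine rescaling of a variable", {
  d <- species_data(seed = 73, driver_vars = c("Bio1", "Bio12"),
                    n_clean = 80, n_bg = 400)
  vars <- c("Bio1", "Bio4", "Bio12")
  imp1 <- jackknife_importance(d$pv[, vars], d$bv[, vars], n_knots = 6,
                               with_only = FALSE)
  pv2 <- d$pv[, vars]; bv2 <- d$bv[, vars]
  pv2[, "Bio12"] <- pv2[, "Bio12"] / 100 + 3
  bv2[, "Bio12"] <- bv2[, "Bio12"] / 100 + 3
  imp2 <- jackknife_importance(pv2, bv2, n_knots = 6, with_only = FALSE)
  expect_equal(imp1$percent, imp2$percent, tolerance = 1e-6)
})

test_that("select_top_variables ranks by cross-species mean with canonical tie-breaks", {
  imp <- c(Bio1 = 40, Bio4 = 35, Bio12 = 25)
  expect_identical(select_top_variables(imp, 2), c("Bio1", "Bio4"))
  expect_identical(select_top_variables(imp, 3), c("Bio1", "Bio4", "Bio12"))
  # ties broken by canonical table order
  tie <- c(Bio12 = 30, Bio4 = 30, Bio1 = 40)
  expect_identical(select_top_variables(tie, 2), c("Bio1", "Bio4"))
  # permuting species order leaves the selection unchanged
  a <- data.frame(variable = c("Bio1", "Bio4"), percent = c(80, 20))
  b <- data.frame(variable = c("Bio1", "Bio4"), percent = c(30, 70))
  expect_identical(select_top_variables(list(a, b), 1),
                   select_top_variables(list(b, a), 1))
})

test_that("variable_change computes zonal mean differences (masked oracle)", {
  grid <- grid_spec(20, 24)
  cur <- generate_climate(grid, seed = 74)
  em <- generate_ecoregions(grid, 12, freshwater_biomes, seed = 75)
  # future == current: all CV zero
  cv0 <- variable_change(cur, cur, em, "Bio1")
  expect_true(all(cv0$cv == 0))
  # uniform +2 on Bio1: every ecoregion's CV is exactly 2
  fut <- apply_scenario(cur, scenario_delta(list(Bio1 = 2), "RCP4.5"))
  cv2 <- variable_change(cur, fut, em, "Bio1")
  expect_equal(cv2$cv, rep(2, 12), tolerance = 1e-12)
  # random fields against a masked-mean oracle
  futr <- apply_scenario(cur, generate_scenario_delta(grid, 76,
                                                      scenario = "RCP4.5"))
  cvr <- variable_change(cur, futr, em, "Bio4")
  for (id in cvr$ecoregion_id) {
    mask <- em$labels == id
    expect_equal(cvr$cv[cvr$ecoregion_id == id],
                 mean(futr$layers$Bio4[mask]) - mean(cur$layers$Bio4[mask]),
                 tolerance = 1e-12)
  }
})

test_that("potential_vs_change_regression matches closed-form OLS and flags degenerate biomes", {
  set.seed(77)
  n <- 30
  cv <- data.frame(ecoregion_id = 1:n, biome = "TBMF",
                   realm = "terrestrial", cv = rnorm(n))
  # noiseless linear potential: R^2 -> 1
  pots <- data.frame(ecoregion_id = 1:n, biome = "TBMF",
                     potential = 3 * cv$cv, included = TRUE)
  res <- suppressWarnings(potential_vs_change_regression(pots, cv))
  expect_equal(res$r_squared, 1, tolerance = 1e-9)
  expect_equal(res$slope, 3, tolerance = 1e-9)
  # 4-point hand case
  cv4 <- data.frame(ecoregion_id = 1:4, biome = "TCF", realm = "t",
                    cv = c(1, 2, 3, 4))
  p4 <- data.frame(ecoregion_id = 1:4, biome = "TCF",
                   potential = c(1.2, 1.9, 3.4, 3.7), included = TRUE)
  got <- potential_vs_change_regression(p4, cv4)
  ora <- ols_oracle(cv4$cv, p4$potential)
  expect_equal(got$r_squared, ora$r_squared, tolerance = 1e-10)
  expect_equal(got$p_value, ora$p_value, tolerance = 1e-10)
  # null case: p approximately uniform
  set.seed(78)
  ps <- replicate(100, {
    cvn <- data.frame(ecoregion_id = 1:100, biome = "BF", realm = "t",
                      cv = rnorm(100))
    pn <- data.frame(ecoregion_id = 1:100, biome = "BF",
                     potential = rnorm(100), included = TRUE)
    potential_vs_change_regression(pn, cvn)$p_value
  })
  expect_lt(mean(ps < 0.05), 0.12)
  # degenerate biomes are flagged, not dropped
  small <- potential_vs_change_regression(p4[1:2, ], cv4[1:2, ])
  expect_identical(small$flag, "too_few")
  cvz <- cv4; cvz$cv <- 1
  zv <- potential_vs_change_regression(p4, cvz)
  expect_identical(zv$flag, "zero_variance")
})

test_that("planted-slope regressions achieve nominal 2-SE coverage", {
  set.seed(79)
  hits <- replicate(200, {
    x <- rnorm(100)
    y <- 1.5 * x + rnorm(100)
    fit <- stats::lm(y ~ x)
    est <- stats::coef(fit)[2]
    se <- summary(fit)$coefficients[2, 2]
    abs(est - 1.5) <= 2 * se
  })
  expect_gte(mean(hits), 0.93)
})

test_that("biome_change_summary reports per-biome mean and sample SD over included ecoregions", {
  cv <- data.frame(ecoregion_id = 1:6,
                   biome = c("LL", "LL", "LL", "PF", "PF", "TCR"),
                   cv = c(1, 2, 3, 5, 5, 9))
  pots <- data.frame(ecoregion_id = 1:6,
                     included = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  s <- biome_change_summary(cv, pots)
  expect_equal(s$mean_cv[s$biome == "LL"], 2)
  expect_equal(s$sd_cv[s$biome == "LL"], stats::sd(c(1, 2, 3)))
  # identical CVs: SD 0
  expect_equal(s$sd_cv[s$biome == "PF"], 0)
  # excluded ecoregions do not appear
  expect_false("TCR" %in% s$biome)
  # one included ecoregion per biome: mean = its CV, SD undefined
  pots1 <- data.frame(ecoregion_id = 1:6,
                      included = c(TRUE, FALSE, FALSE, TRUE, FALSE, TRUE))
  s1 <- biome_change_summary(cv, pots1)
  expect_equal(s1$mean_cv[s1$biome == "LL"], 1)
  expect_true(is.na(s1$sd_cv[s1$biome == "LL"]))
  # random case against a direct two-pass oracle
  set.seed(80)
  cvr <- data.frame(ecoregion_id = 1:40,
                    biome = sample(c("MF", "OI"), 40, replace = TRUE),
                    cv = rnorm(40))
  potr <- data.frame(ecoregion_id = 1:40,
                     included = sample(c(TRUE, FALSE), 40, replace = TRUE))
  sr <- biome_change_summary(cvr, potr)
  for (b in sr$biome) {
    vals <- cvr$cv[cvr$biome == b & potr$included]
    expect_equal(sr$mean_cv[sr$biome == b], mean(vals))
    expect_equal(sr$sd_cv[sr$biome == b], stats::sd(vals))
  }
})
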