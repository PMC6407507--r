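test_that("uniform-bandwidth background is uniform over eligible pixels (chi-square GOF)", {
  grid <- grid_spec(120, 120)
  occ <- data.frame(lon = 1, lat = 1)
  bg <- sample_background(occ, grid, n_max = 10000, bias_bandwidth = Inf,
                          seed = 3)
  expect_identical(nrow(bg), 10000L)
  expect_identical(anyDuplicated(paste(bg$row, bg$col)), 0L)
  # 8x8 blocks of 15x15 pixels each
  bin <- paste((bg$row - 1) %/% 15, (bg$col - 1) %/% 15)
  obs <- table(factor(bin, levels = unique(paste(
    rep(0:7, each = 8), rep(0:7, 8)))))
  gof <- stats::chisq.test(as.vector(obs))
  expect_gt(gof$p.value, 0.01)
})

test_that("biased background concentrates near the occurrences", {
  grid <- grid_spec(40, 40)
  set.seed(5)
  # all occurrences in the south-west quadrant
  occ <- data.frame(lon = runif(60, 0.2, 2.8), lat = runif(60, 0.2, 2.8))
  bg <- sample_background(occ, grid, n_max = 400, bias_bandwidth = 2,
                          seed = 9)
  in_quadrant <- mean(bg$row <= 20 & bg$col <= 20)
  expect_gt(in_quadrant, 0.8)
  # determinism
  expect_identical(bg, sample_background(occ, grid, n_max = 400,
                                         bias_bandwidth = 2, seed = 9))
})

test_that("n_max above the pixel count returns every pixel once, with a warning", {
  grid <- grid_spec(6, 7)
  occ <- data.frame(lon = 0.5, lat = 0.5)
  expect_warning(bg <- sample_background(occ, grid, n_max = 100), "taking all")
  expect_identical(nrow(bg), 42L)
  expect_identical(anyDuplicated(paste(bg$row, bg$col)), 0L)
})

test_that("hinge features satisfy their definitions and match a direct oracle", {
  set.seed(11)
  x <- matrix(runif(200, -3, 7), ncol = 1,
              dimnames = list(NULL, "Bio1"))
  hf <- build_hinge_features(x, n_knots_per_variable = 5)
  fs <- hf$featureset
  sp <- fs$spec$Bio1
  expect_true(all(diff(sp$knots) > 0))
  # x equal to a knot: both hinges at that knot evaluate to 0
  k <- sp$knots[3]
  d <- design_matrix(fs, matrix(k, 1, 1, dimnames = list(NULL, "Bio1")))
  expect_equal(unname(d[1, "Bio1:L3"]), 0)
  expect_equal(unname(d[1, "Bio1:R3"]), 0)
  # x at the variable max: every left hinge equals 1
  dmax <- design_matrix(fs, matrix(sp$vmax, 1, 1,
                                   dimnames = list(NULL, "Bio1")))
  for (j in seq_along(sp$knots)) {
    expect_equal(unname(dmax[1, paste0("Bio1:L", j)]), 1)
  }
  # entries match an independent per-element recomputation
  oracle <- function(xi) {
    xi <- unname(xi)
    out <- c((xi - sp$vmin) / (sp$vmax - sp$vmin))
    for (k in sp$knots) {
      out <- c(out, max(0, (xi - k) / (sp$vmax - k)),
               max(0, (k - xi) / (k - sp$vmin)))
    }
    out
  }
  D <- hf$design
  for (i in c(1, 17, 50, 200)) {
    expect_equal(unname(D[i, ]), oracle(x[i, 1]), tolerance = 1e-12)
  }
  expect_true(all(D >= 0 & D <= 1))
  # constant variable: no features, with a warning
  const <- matrix(2, 10, 1, dimnames = list(NULL, "Bio2"))
  expect_warning(h0 <- build_hinge_features(const), "constant variable")
  expect_identical(ncol(h0$design), 0L)
})

test_that("extreme regularisation shrinks all weights to zero and H = log(n_background)", {
  set.seed(13)
  Xp <- matrix(runif(40), 10, 4)
  Xb <- matrix(runif(200), 50, 4)
  m <- fit_maxent(Xp, Xb, beta = 1e6)
  expect_true(all(m$lambda == 0))
  expect_equal(m$H, log(50), tolerance = 1e-9)
  expect_equal(sum(m$bg_raw), 1, tolerance = 1e-12)
})

test_that("the solver trace is monotone and the solution beats lambda = 0", {
  w <- small_world(seed = 17, nr = 24, nc = 36)
  occ <- sample_occurrences(w$niches[[1]], w$current, n_clean = 120, seed = 1)
  pv <- extract_values(occ, w$current)
  bg <- sample_background(occ, w$grid, n_max = 500, seed = 2)
  bv <- extract_values(bg, w$current)
  hf <- build_hinge_features(rbind(pv, bv), n_knots_per_variable = 8)
  Xp <- design_matrix(hf$featureset, pv)
  Xb <- design_matrix(hf$featureset, bv)
  m <- fit_maxent(Xp, Xb)
  expect_true(all(diff(m$trace) <= 1e-12))
  # objective at lambda = 0 equals log(n_background); solution is lower
  expect_lte(m$trace[length(m$trace)], log(nrow(Xb)))
  expect_true(m$converged)
  # raw sums to 1 over the background, fitted model
  expect_equal(sum(m$bg_raw), 1, tolerance = 1e-9)
})

test_that("fitting recovers a known single-hinge Gibbs density (Spearman >= 0.95)", {
  set.seed(19)
  n_bg <- 2000
  xb <- sort(runif(n_bg, 0, 10))
  hinge <- pmax(0, (xb - 4) / (10 - 4))
  q_true <- exp(3 * hinge)
  q_true <- q_true / sum(q_true)
  pres_idx <- sample(n_bg, 1000, replace = TRUE, prob = q_true)
  pv <- matrix(xb[pres_idx], ncol = 1, dimnames = list(NULL, "Bio1"))
  bv <- matrix(xb, ncol = 1, dimnames = list(NULL, "Bio1"))
  m <- train_sdm(pv, bv, beta = 1.5, n_knots = 10)
  raw <- score_values <- predict(m, bv, type = "raw")
  expect_gt(stats::cor(raw, q_true, method = "spearman"), 0.95)
})

test_that("prediction scales behave as documented", {
  # hand toy for the cumulative transform
  bg_raw <- c(0.1, 0.1, 0.2, 0.25, 0.35)
  expect_equal(cumulative_transform(bg_raw, bg_raw), c(20, 20, 40, 65, 100))
  expect_equal(cumulative_transform(0.05, bg_raw), 0)

  w <- small_world(seed = 23, nr = 20, nc = 30)
  occ <- sample_occurrences(w$niches[[1]], w$current, n_clean = 60, seed = 1)
  pv <- extract_values(occ, w$current)
  bg <- sample_background(occ, w$grid, n_max = 300, seed = 2)
  bv <- extract_values(bg, w$current)
  m <- train_sdm(pv, bv, n_knots = 6)
  # raw map sums to 1 over the background pixels for the projected model
  raw_bg <- predict(m, bv, type = "raw")
  expect_equal(sum(raw_bg), 1, tolerance = 1e-9)
  # logistic is a strictly increasing transform of raw
  raw_map <- predict(m, w$current, type = "raw")
  logi_map <- predict(m, w$current, type = "logistic")
  o <- order(as.vector(raw_map))
  expect_true(all(diff(as.vector(logi_map)[o]) >= 0))
  expect_true(all(logi_map > 0 & logi_map < 1))
  # cumulative of the maximum-raw background pixel is 100
  expect_equal(max(predict(m, bv, type = "cumulative")), 100)
  # projecting onto an identical copy of the training stack is bit-identical
  copy <- w$current
  expect_identical(predict(m, copy, type = "logistic"), logi_map)
  # a uniform model scores every pixel identically
  mu <- fit_maxent(design_matrix(m$featureset, pv),
                   design_matrix(m$featureset, bv), beta = 1e6,
                   featureset = m$featureset)
  lu <- predict(mu, w$current, type = "logistic")
  expect_equal(max(lu) - min(lu), 0, tolerance = 1e-12)
  # missing variable in the projection stack is rejected
  expect_error(predict(m, subset_stack(w$current, c("Bio1", "Bio2")),
                       type = "raw"),
               "lacks model variable")
})

test_that("cross_validate partitions presences deterministically and averages fold maps", {
  w <- small_world(seed = 29, nr = 24, nc = 36)
  occ <- sample_occurrences(w$niches[[1]], w$current, n_clean = 60, seed = 1)
  cv <- cross_validate(occ, w$current, k = 3, seed = 7, n_knots = 5,
                       n_background = 300)
  expect_identical(sort(unique(cv$folds)), 1:3)
  expect_true(all(table(cv$folds) == 20))
  cv2 <- cross_validate(occ, w$current, k = 3, seed = 7, n_knots = 5,
                        n_background = 300)
  expect_identical(cv$folds, cv2$folds)
  expect_identical(cv$mean_map, cv2$mean_map)
  # averaged map equals the per-pixel mean of independently recomputed maps
  maps <- lapply(cv$models, predict, newdata = w$current, type = "logistic")
  expect_equal(cv$mean_map, (maps[[1]] + maps[[2]] + maps[[3]]) / 3,
               tolerance = 1e-12)
  # fold-count contract
  four <- occ[1:4, ]
  cv4 <- cross_validate(four, w$current, k = 2, seed = 1, n_knots = 4,
                        n_background = 200)
  expect_true(all(table(cv4$folds) == 2))
  expect_error(cross_validate(four, w$current, k = 1), "2 <= k")
  expect_error(cross_validate(four, w$current, k = 5), "2 <= k")
})
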