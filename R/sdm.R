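#' @title Presence-background maximum-entropy suitability models
#' @description The modelling stage: bias-aware background sampling, hinge
#'   feature construction, L1-penalised Gibbs-density fitting, projection as
#'   raw / cumulative / logistic suitability, and k-fold cross-validation.
#'
#'   The model estimates a density over the landscape,
#'   `q(x) = exp(sum_f lambda_f f(x)) / Z`, with `Z` normalised over the
#'   background sample, by minimising the penalised negative log-likelihood
#'   of the presences: `-mean(lambda . f(x_i)) + log Z +
#'   sum_f beta * s_f / sqrt(m) * |lambda_f|`, where `s_f` is the feature's
#'   standard deviation over the presences and `m` the presence count. This
#'   is the standard maximum-entropy formulation with hinge features and
#'   regularisation multiplier `beta` (default 1.5).
#' @name sdm
NULL

# --- background ------------------------------------------------------------

#' Sample background (pseudo-absence) pixels
#'
#' Pixels are drawn without replacement with probability proportional to a
#' Gaussian-smoothed occurrence-density surface, so the background stays
#' close to the geographic (and hence environmental) space that holds the
#' occurrence sample; `bias_bandwidth = Inf` recovers a uniform background.
#' A vanishing floor keeps every usable pixel eligible.
#'
#' @param occurrences Data.frame with `lon`, `lat` for the target species.
#' @param grid A [grid_spec()].
#' @param n_max Maximum number of background pixels (default 10000).
#' @param bias_bandwidth Kernel SD in pixels; `Inf` for uniform.
#' @param seed Integer seed.
#' @return A data.frame of class `background_sample` with columns `row`,
#'   `col`, `lon`, `lat` (pixel centres), one row per sampled pixel.
#' @export
sample_background <- function(occurrences, grid, n_max = 10000,
                              bias_bandwidth = Inf, seed = 1L) {
  stopifnot(inherits(grid, "grid_spec"), n_max >= 1)
  ok <- usable_mask(grid)
  eligible <- which(ok)
  with_seed(child_seed(seed, 7L), {
    if (length(eligible) <= n_max) {
      if (length(eligible) < n_max) {
        warning("fewer eligible pixels (", length(eligible),
                ") than n_max; taking all")
      }
      cells <- eligible
    } else if (is.infinite(bias_bandwidth)) {
      cells <- sample(eligible, n_max)
    } else {
      stopifnot(bias_bandwidth > 0)
      counts <- matrix(0, grid$n_rows, grid$n_cols)
      idx <- cell_index(grid, occurrences$lon, occurrences$lat)
      inside <- !is.na(idx$row)
      for (i in which(inside)) {
        counts[idx$row[i], idx$col[i]] <- counts[idx$row[i], idx$col[i]] + 1
      }
      dens <- smooth_field(counts, bias_bandwidth)
      dens <- pmax(dens, 0) + 1e-12 * max(dens, 1)
      cells <- sample(eligible, n_max, prob = dens[eligible])
    }
    cells <- sort(cells)
    r <- ((cells - 1L) %% grid$n_rows) + 1L
    cc <- ((cells - 1L) %/% grid$n_rows) + 1L
    ctr <- cell_center(grid, r, cc)
    structure(data.frame(row = r, col = cc, lon = ctr$lon, lat = ctr$lat),
              class = c("background_sample", "data.frame"),
              bias_bandwidth = bias_bandwidth)
  })
}

# --- hinge features --------------------------------------------------------

#' Build hinge features for a set of climate variables
#'
#' For each variable, knots are placed at empirical quantiles of the combined
#' presence + background sample; each interior knot `k` contributes a left
#' hinge `max(0, (x - k) / (max - k))` and a right hinge
#' `max(0, (k - x) / (k - min))`, and the raw linear term is min-max scaled.
#' All features lie in `[0, 1]` over the training range. Constant variables
#' contribute no features (with a warning).
#'
#' @param values Numeric matrix (samples x variables) with Bio-code column
#'   names, typically from [extract_values()].
#' @param n_knots_per_variable Number of quantile knots per variable
#'   (default 20).
#' @return A list with `featureset` (class `feature_set`: per-variable range
#'   and knots) and `design` (the feature matrix for `values`).
#' @export
build_hinge_features <- function(values, n_knots_per_variable = 20) {
  stopifnot(is.matrix(values), !is.null(colnames(values)))
  vars <- colnames(values)
  spec <- lapply(vars, function(v) {
    x <- values[, v]
    x <- x[is.finite(x)]
    vmin <- min(x); vmax <- max(x)
    if (vmax <= vmin) {
      warning("constant variable '", v, "': no features built")
      return(list(vmin = vmin, vmax = vmax, knots = numeric(0)))
    }
    k <- stats::quantile(x, seq_len(n_knots_per_variable) /
                           (n_knots_per_variable + 1), names = FALSE)
    k <- sort(unique(k))
    k <- k[k > vmin & k < vmax]
    list(vmin = vmin, vmax = vmax, knots = k)
  })
  names(spec) <- vars
  fs <- structure(list(variables = vars, spec = spec,
                       n_knots = n_knots_per_variable),
                  class = "feature_set")
  list(featureset = fs, design = design_matrix(fs, values))
}

#' Evaluate a feature set on climate values
#'
#' Values are clamped to the training range of each variable before the
#' hinges are evaluated, so projection outside the training envelope holds
#' the response at its boundary value rather than extrapolating.
#'
#' @param featureset A `feature_set` from [build_hinge_features()].
#' @param values Numeric matrix (samples x variables) containing every
#'   feature-set variable as a named column.
#' @param clamp Clamp to the training range (default TRUE).
#' @return Numeric design matrix (samples x features), entries in `[0, 1]`.
#' @export
design_matrix <- function(featureset, values, clamp = TRUE) {
  stopifnot(inherits(featureset, "feature_set"), is.matrix(values))
  miss <- setdiff(featureset$variables, colnames(values))
  if (length(miss)) stop("values lack variable(s): ",
                         paste(miss, collapse = ", "))
  cols <- list(); nms <- character(0)
  for (v in featureset$variables) {
    s <- featureset$spec[[v]]
    if (!length(s$knots) && s$vmax <= s$vmin) next
    x <- values[, v]
    if (clamp) x <- pmin(pmax(x, s$vmin), s$vmax)
    cols[[length(cols) + 1L]] <- (x - s$vmin) / (s$vmax - s$vmin)
    nms <- c(nms, paste0(v, ":linear"))
    for (j in seq_along(s$knots)) {
      k <- s$knots[j]
      cols[[length(cols) + 1L]] <- pmax(0, (x - k) / (s$vmax - k))
      cols[[length(cols) + 1L]] <- pmax(0, (k - x) / (k - s$vmin))
      nms <- c(nms, paste0(v, ":L", j), paste0(v, ":R", j))
    }
  }
  if (!length(cols)) {
    return(matrix(numeric(0), nrow = nrow(values), ncol = 0))
  }
  out <- do.call(cbind, cols)
  colnames(out) <- nms
  out
}

# --- fitting ---------------------------------------------------------------

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Fit a maximum-entropy suitability model
#'
#' Minimises the L1-penalised negative log-likelihood of the presences under
#' the Gibbs density normalised over the background (see the module
#' description) with a monotone accelerated proximal-gradient solver. The
#' objective trace is stored on the model and is non-increasing.
#'
#' @param presence_features,background_features Design matrices from
#'   [design_matrix()] with identical columns; at least 1 presence and 2
#'   background rows.
#' @param beta Regularisation multiplier (default 1.5).
#' @param tol Convergence tolerance on the KKT optimality measure
#'   (max-norm of the projected subgradient).
#' @param max_iter Iteration cap; non-convergence is an error carrying the
#'   final optimality measure.
#' @param featureset Optional `feature_set` attached to the model so it can
#'   predict from raw climate values.
#' @return An object of class `maxent_model`: weights `lambda`, `beta`,
#'   penalty weights, log-normaliser `logZ`, entropy `H` of the fitted
#'   density over the background, the background raw distribution `bg_raw`,
#'   and the solver trace.
#' @export
fit_maxent <- function(presence_features, background_features, beta = 1.5,
                       tol = 1e-4, max_iter = 3000, featureset = NULL) {
  Xp <- as.matrix(presence_features)
  Xb <- as.matrix(background_features)
  m <- nrow(Xp); n <- nrow(Xb); p <- ncol(Xb)
  stopifnot(m >= 1, n >= 2, ncol(Xp) == p)
  s <- apply(Xp, 2, stats::sd)
  s[!is.finite(s)] <- 0
  # the floor on s is the minimum-regularisation safeguard: features almost
  # constant over the presences would otherwise be near-unpenalised, and
  # quasi-separable fits diverge
  pen <- beta * pmax(s, 0.05) / sqrt(m)
  fbar <- colMeans(Xp)

  nll <- function(lam) {
    eta <- drop(Xb %*% lam)
    -sum(fbar * lam) + logsumexp(eta)
  }
  grad_q <- function(lam) {
    eta <- drop(Xb %*% lam)
    lz <- logsumexp(eta)
    q <- exp(eta - lz)
    list(g = drop(crossprod(Xb, q)) - fbar, q = q, lz = lz)
  }
  obj <- function(lam) nll(lam) + sum(pen * abs(lam))
  soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

  lam <- numeric(p)
  y <- lam
  t_acc <- 1
  L <- 1
  f_x <- nll(lam)
  F_x <- obj(lam)
  trace <- F_x
  kkt <- Inf
  for (it in seq_len(max_iter)) {
    gq <- grad_q(y)
    f_y <- -sum(fbar * y) + gq$lz
    repeat {  # backtracking on the smooth part
      z <- soft(y - gq$g / L, pen / L)
      dz <- z - y
      f_z <- nll(z)
      if (f_z <= f_y + sum(gq$g * dz) + L / 2 * sum(dz^2) + 1e-12) break
      L <- 2 * L
    }
    F_z <- f_z + sum(pen * abs(z))
    if (F_z > F_x) {  # monotone safeguard: plain step from the best iterate
      gx <- grad_q(lam)
      f_lam <- -sum(fbar * lam) + gx$lz
      repeat {
        z <- soft(lam - gx$g / L, pen / L)
        dz <- z - lam
        f_z <- nll(z)
        if (f_z <= f_lam + sum(gx$g * dz) + L / 2 * sum(dz^2) + 1e-12) break
        L <- 2 * L
      }
      F_z <- f_z + sum(pen * abs(z))
      t_acc <- 1  # restart acceleration
    }
    t_next <- (1 + sqrt(1 + 4 * t_acc^2)) / 2
    y <- z + ((t_acc - 1) / t_next) * (z - lam)
    lam_prev <- lam
    lam <- z
    t_acc <- t_next
    F_x <- min(F_x, F_z)
    trace <- c(trace, F_x)
    gz <- grad_q(lam)$g
    kkt <- max(ifelse(lam != 0, abs(gz + sign(lam) * pen),
                      pmax(abs(gz) - pen, 0)))
    if (kkt < tol) break
    L <- max(L / 2, 1e-3)  # allow the step to grow again
  }
  if (kkt >= tol) {
    stop(sprintf(paste0("maxent solver did not converge in %d iterations ",
                        "(KKT optimality %.3g > tol %.3g)"),
                 max_iter, kkt, tol))
  }
  gq <- grad_q(lam)
  H <- -sum(gq$q * log(pmax(gq$q, .Machine$double.xmin)))
  structure(list(lambda = stats::setNames(lam, colnames(Xb)), beta = beta,
                 penalty = pen, feature_sd = s, n_presence = m,
                 n_background = n, logZ = gq$lz,
                 H = H, bg_raw = gq$q, featureset = featureset,
                 trace = trace, iterations = length(trace) - 1L,
                 kkt = kkt, converged = TRUE),
            class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(paste0("<maxent_model> %d features (%d active), beta %.2f, ",
                     "H %.3f, %d iterations\n"),
              length(x$lambda), sum(x$lambda != 0), x$beta, x$H,
              x$iterations))
  invisible(x)
}

#' Train a maxent model from raw climate values
#'
#' Convenience wrapper: builds hinge features on the combined presence and
#' background values, fits the model and attaches the feature set.
#'
#' @param presence_values,background_values Matrices of climate values
#'   (rows x Bio-code columns).
#' @param beta,n_knots,tol,max_iter Passed through.
#' @return A `maxent_model` with its `featureset` attached.
#' @export
train_sdm <- function(presence_values, background_values, beta = 1.5,
                      n_knots = 20, tol = 1e-4, max_iter = 3000) {
  hf <- build_hinge_features(rbind(presence_values, background_values),
                             n_knots_per_variable = n_knots)
  Xp <- design_matrix(hf$featureset, presence_values)
  Xb <- design_matrix(hf$featureset, background_values)
  fit_maxent(Xp, Xb, beta = beta, tol = tol, max_iter = max_iter,
             featureset = hf$featureset)
}

# --- prediction ------------------------------------------------------------

#' Cumulative transform of raw suitability values
#'
#' `cumulative(x) = 100 * sum of the raw probability mass of background
#' points whose raw value is <= raw(x)`; the background's own maximum raw
#' value therefore maps to 100.
#'
#' @param raw Numeric vector of raw (Gibbs density) values to transform.
#' @param bg_raw Raw values of the background sample (summing to 1).
#' @return Numeric vector in `[0, 100]`.
#' @export
cumulative_transform <- function(raw, bg_raw) {
  o <- order(bg_raw)
  srt <- bg_raw[o]
  cs <- cumsum(srt)
  pos <- findInterval(raw, srt)
  100 * c(0, cs)[pos + 1L]
}

#' Project a fitted model as a suitability map or score vector
#'
#' Raw output is the Gibbs density normalised over the *training*
#' background (`exp(eta - logZ)`), so raw values over the training
#' background sum to 1. Cumulative output applies
#' [cumulative_transform()] against the training background. Logistic
#' output is `e^H * q / (1 + e^H * q)`, the entropy-calibrated transform,
#' strictly increasing in the raw value and valued in (0, 1). Feature
#' values are clamped to the training range.
#'
#' @param object A `maxent_model` with an attached feature set.
#' @param newdata A `climate_stack` (returns a matrix map, NA on nodata) or
#'   a matrix of climate values (returns a vector).
#' @param type One of `"logistic"`, `"raw"`, `"cumulative"`.
#' @param ... Unused.
#' @return Matrix map or numeric vector of suitability scores.
#' @export
predict.maxent_model <- function(object, newdata,
                                 type = c("logistic", "raw", "cumulative"),
                                 ...) {
  type <- match.arg(type)
  if (is.null(object$featureset)) {
    stop("model has no feature set; fit via train_sdm() or attach one")
  }
  if (inherits(newdata, "climate_stack")) {
    miss <- setdiff(object$featureset$variables, stack_variables(newdata))
    if (length(miss)) stop("stack lacks model variable(s): ",
                           paste(miss, collapse = ", "))
    g <- newdata$grid
    vals <- vapply(object$featureset$variables,
                   function(v) as.vector(newdata$layers[[v]]),
                   numeric(n_cells(g)))
    okrow <- stats::complete.cases(vals)
    out <- rep(NA_real_, n_cells(g))
    if (any(okrow)) {
      out[okrow] <- score_values(object, vals[okrow, , drop = FALSE], type)
    }
    return(matrix(out, g$n_rows, g$n_cols))
  }
  score_values(object, as.matrix(newdata), type)
}

score_values <- function(model, values, type) {
  X <- design_matrix(model$featureset, values, clamp = TRUE)
  eta <- drop(X %*% model$lambda[colnames(X)])
  raw <- exp(eta - model$logZ)
  switch(type,
         raw = raw,
         cumulative = cumulative_transform(raw, model$bg_raw),
         logistic = {
           z <- exp(model$H) * raw
           z / (1 + z)
         })
}

# --- cross-validation ------------------------------------------------------

#' Cross-validated suitability modelling for one species
#'
#' Presences are partitioned into `k` disjoint folds; each fold's model is
#' trained on the other `k - 1` folds against a shared background sample,
#' and the species' suitability map is the per-pixel mean of the `k`
#' fold-model logistic maps. Fold membership, per-fold models and the
#' presence/background data are retained for evaluation.
#'
#' @param occurrences Cleaned occurrence data.frame (`lon`, `lat`) for one
#'   species.
#' @param stack Training-scenario `climate_stack` (already restricted to the
#'   retained variables).
#' @param k Number of folds (default 10); must satisfy `2 <= k <=`
#'   presence count.
#' @param seed Integer seed (fold partition and background sample).
#' @param beta,n_knots,tol,max_iter Model settings, see [fit_maxent()].
#' @param n_background,bias_bandwidth Background settings, see
#'   [sample_background()].
#' @param background Optional precomputed [sample_background()] result.
#' @return An object of class `sdm_cv`: `mean_map`, `models` (length `k`),
#'   `folds` (fold id per presence), `presence_values`, `background`,
#'   `background_values`, `grid`, and the settings used.
#' @export
cross_validate <- function(occurrences, stack, k = 10, seed = 1L,
                           beta = 1.5, n_knots = 20, tol = 1e-4,
                           max_iter = 3000, n_background = 10000,
                           bias_bandwidth = Inf, background = NULL) {
  stopifnot(inherits(stack, "climate_stack"))
  pv <- extract_values(occurrences, stack)
  keep <- !attr(pv, "excluded")
  pv <- pv[keep, , drop = FALSE]
  m <- nrow(pv)
  if (k < 2 || k > m) stop("k must satisfy 2 <= k <= number of presences")
  if (is.null(background)) {
    background <- sample_background(occurrences[keep, , drop = FALSE],
                                    stack$grid, n_max = n_background,
                                    bias_bandwidth = bias_bandwidth,
                                    seed = seed)
  }
  bv <- extract_values(background, stack)
  bv <- bv[!attr(bv, "excluded"), , drop = FALSE]
  folds <- with_seed(child_seed(seed, 8L),
                     sample(rep(seq_len(k), length.out = m)))
  models <- vector("list", k)
  maps <- vector("list", k)
  for (j in seq_len(k)) {
    tr <- folds != j
    models[[j]] <- train_sdm(pv[tr, , drop = FALSE], bv, beta = beta,
                             n_knots = n_knots, tol = tol,
                             max_iter = max_iter)
    maps[[j]] <- predict(models[[j]], stack, type = "logistic")
  }
  mean_map <- Reduce(`+`, maps) / k
  structure(list(mean_map = mean_map, models = models, folds = folds,
                 presence_values = pv, background = background,
                 background_values = bv, grid = stack$grid, k = k,
                 seed = seed, beta = beta, n_knots = n_knots),
            class = "sdm_cv")
}

#' @export
print.sdm_cv <- function(x, ...) {
  cat(sprintf("<sdm_cv> %d folds, %d presences, %d background pixels\n",
              x$k, nrow(x$presence_values), nrow(x$background_values)))
  invisible(x)
}

#' Mean logistic projection of a cross-validated model onto a stack
#'
#' @param cv An `sdm_cv` object.
#' @param stack A `climate_stack` carrying the model variables.
#' @param type Output scale (default logistic).
#' @return Matrix map: per-pixel mean over the fold models.
#' @export
project_cv <- function(cv, stack, type = "logistic") {
  maps <- lapply(cv$models, predict, newdata = stack, type = type)
  Reduce(`+`, maps) / length(maps)
}
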