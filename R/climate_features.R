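#' @title Climate-feature attribution
#' @description Which climate variables drive the modelled suitability and
#'   how their change relates to expansion potential: jackknife variable
#'   importance (gain drop when a variable is withheld), per-ecoregion
#'   change of a variable's zonal mean (`CV_n = V_n^f - V_n^c`), per-biome
#'   regressions of potential on that change, and per-biome mean/SD
#'   summaries over ecoregions with expansion potential.
#' @name climate_features
NULL

# unregularised training gain of a fitted model: mean presence
# log-likelihood above the uniform-background baseline
model_gain <- function(model, presence_values) {
  raw <- score_values(model, presence_values, "raw")
  mean(log(pmax(raw, .Machine$double.xmin))) + log(model$n_background)
}

#' Jackknife variable importance for one species
#'
#' The full model is refit withholding each variable in turn; a variable's
#' raw importance is the drop in training gain, `max(0, G_full - G_-v)`,
#' and percent contributions are raw importances normalised to sum to 100.
#' With-only gains (model using the single variable) are reported alongside.
#' Quantile-based hinge knots make the result invariant to affine rescaling
#' of any input variable.
#'
#' @param presence_values,background_values Climate value matrices
#'   (rows x Bio-code columns) for the species.
#' @param beta,n_knots,tol,max_iter Model settings, see [fit_maxent()].
#' @param with_only Also fit single-variable models (default TRUE).
#' @return A data.frame of class `variable_importance`: `variable`,
#'   `gain_drop`, `percent` (sums to 100), `gain_only`; attribute
#'   `gain_full`.
#' @export
jackknife_importance <- function(presence_values, background_values,
                                 beta = 1.5, n_knots = 20, tol = 1e-4,
                                 max_iter = 3000, with_only = TRUE) {
  vars <- colnames(presence_values)
  stopifnot(!is.null(vars), identical(vars, colnames(background_values)))
  fit_on <- function(v) {
    train_sdm(presence_values[, v, drop = FALSE],
              background_values[, v, drop = FALSE],
              beta = beta, n_knots = n_knots, tol = tol,
              max_iter = max_iter)
  }
  full <- fit_on(vars)
  g_full <- model_gain(full, presence_values)
  if (length(vars) == 1L) {
    out <- data.frame(variable = vars, gain_drop = g_full, percent = 100,
                      gain_only = g_full)
  } else {
    drops <- vapply(vars, function(v) {
      keep <- setdiff(vars, v)
      m <- fit_on(keep)
      max(0, g_full - model_gain(m, presence_values[, keep, drop = FALSE]))
    }, numeric(1))
    pct <- if (sum(drops) > 0) 100 * drops / sum(drops)
           else rep(100 / length(vars), length(vars))
    only <- if (with_only) {
      vapply(vars, function(v) {
        model_gain(fit_on(v), presence_values[, v, drop = FALSE])
      }, numeric(1))
    } else rep(NA_real_, length(vars))
    out <- data.frame(variable = vars, gain_drop = unname(drops),
                      percent = unname(pct), gain_only = unname(only))
  }
  attr(out, "gain_full") <- g_full
  class(out) <- c("variable_importance", "data.frame")
  out
}

#' Cross-species mean percent contribution
#'
#' @param importances List of per-species [jackknife_importance()] results.
#' @return Named numeric vector: mean percent contribution per variable,
#'   canonical table order.
#' @export
mean_importance <- function(importances) {
  stopifnot(length(importances) >= 1)
  tab <- do.call(rbind, lapply(importances, function(x) {
    stats::setNames(x$percent, x$variable)
  }))
  out <- colMeans(tab)
  out[intersect(bio_variables, names(out))]
}

#' Select the most important climate variables
#'
#' Top-`k` variables by cross-species mean percent contribution, with
#' deterministic ties broken by canonical table order.
#'
#' @param importance Named numeric vector from [mean_importance()] (or a
#'   list of per-species importances, aggregated internally).
#' @param k Number of variables (default 2).
#' @return Character vector of Bio codes.
#' @export
select_top_variables <- function(importance, k = 2) {
  if (is.list(importance) && !is.numeric(importance)) {
    importance <- mean_importance(importance)
  }
  ord <- order(-importance, match(names(importance), bio_variables))
  names(importance)[ord][seq_len(min(k, length(importance)))]
}

#' Per-ecoregion change of a climate variable's zonal mean
#'
#' `V_n` is the unweighted spatial mean of the variable over the
#' ecoregion's usable pixels in each scenario; `CV_n = V_n^f - V_n^c`.
#' Identical stacks give all-zero changes; an empty ecoregion is flagged
#' with `NA`.
#'
#' @param current,future Co-registered `climate_stack`s.
#' @param regions An `ecoregion_map` on the same grid.
#' @param variable A Bio code present in both stacks.
#' @return Data.frame: `ecoregion_id`, `biome`, `realm`, `v_current`,
#'   `v_future`, `cv`.
#' @export
variable_change <- function(current, future, regions, variable) {
  stopifnot(inherits(current, "climate_stack"),
            inherits(future, "climate_stack"),
            inherits(regions, "ecoregion_map"),
            variable %in% stack_variables(current),
            variable %in% stack_variables(future),
            same_grid(current$grid, regions$grid),
            same_grid(future$grid, regions$grid))
  zonal_mean <- function(layer) {
    ok <- !is.na(layer) & !is.na(regions$labels)
    mns <- tapply(layer[ok], regions$labels[ok], mean)
    out <- rep(NA_real_, nrow(regions$meta))
    out[match(as.integer(names(mns)), regions$meta$ecoregion_id)] <-
      as.numeric(mns)
    out
  }
  vc <- zonal_mean(current$layers[[variable]])
  vf <- zonal_mean(future$layers[[variable]])
  if (anyNA(vc)) warning("empty ecoregion(s): zonal mean undefined")
  data.frame(ecoregion_id = regions$meta$ecoregion_id,
             biome = regions$meta$biome, realm = regions$meta$realm,
             v_current = vc, v_future = vf, cv = vf - vc,
             stringsAsFactors = FALSE)
}

#' Per-biome regression of expansion potential on climate change
#'
#' Within each biome, OLS of ecoregion potential on the change `CV_n` of
#' one important variable. Biomes with fewer than 3 usable ecoregions, or
#' zero variance in `CV`, are flagged rather than silently dropped.
#'
#' @param potentials An `expansion_table` (one scenario).
#' @param cv A [variable_change()] table for the same ecoregions.
#' @param included_only Restrict to ecoregions with `included == TRUE`
#'   (default FALSE: all ecoregions with defined potential enter).
#' @return Data.frame: `biome`, `n`, `slope`, `r_squared`, `p_value`,
#'   `flag` (`""`, `"too_few"`, or `"zero_variance"`).
#' @export
potential_vs_change_regression <- function(potentials, cv,
                                           included_only = FALSE) {
  stopifnot(is.data.frame(potentials), is.data.frame(cv))
  d <- merge(potentials[, c("ecoregion_id", "biome", "potential",
                            "included")],
             cv[, c("ecoregion_id", "cv")], by = "ecoregion_id")
  d <- d[is.finite(d$potential) & is.finite(d$cv), ]
  if (included_only) d <- d[d$included %in% TRUE, ]
  rows <- lapply(split(d, d$biome), function(b) {
    out <- data.frame(biome = b$biome[1L], n = nrow(b), slope = NA_real_,
                      r_squared = NA_real_, p_value = NA_real_, flag = "",
                      stringsAsFactors = FALSE)
    if (nrow(b) < 3) {
      out$flag <- "too_few"
    } else if (stats::sd(b$cv) == 0) {
      out$flag <- "zero_variance"
    } else {
      fit <- stats::lm(potential ~ cv, data = b)
      sm <- summary(fit)
      out$slope <- unname(stats::coef(fit)[2L])
      out$r_squared <- sm$r.squared
      out$p_value <- sm$coefficients[2L, 4L]
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-biome mean and SD of climate change over expanding ecoregions
#'
#' Restricted to ecoregions with expansion potential (`included == TRUE`):
#' per biome, the mean and sample standard deviation of `CV_n`. Biomes with
#' fewer than two included ecoregions report `NA` SD.
#'
#' @param cv A [variable_change()] table.
#' @param potentials An `expansion_table` for the same ecoregions.
#' @return Data.frame: `biome`, `n`, `mean_cv`, `sd_cv`.
#' @export
biome_change_summary <- function(cv, potentials) {
  d <- merge(cv[, c("ecoregion_id", "biome", "cv")],
             potentials[, c("ecoregion_id", "included")],
             by = "ecoregion_id")
  d <- d[d$included %in% TRUE & is.finite(d$cv), ]
  rows <- lapply(split(d, d$biome), function(b) {
    data.frame(biome = b$biome[1L], n = nrow(b), mean_cv = mean(b$cv),
               sd_cv = if (nrow(b) >= 2) stats::sd(b$cv) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
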