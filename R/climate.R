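#' @title Bioclimatic stack management
#' @description Collinearity screening of the variable set, multi-model
#'   (GCM) pixel-wise ensembling, and point extraction.
#' @name climate
NULL

#' Screen a variable set for collinearity
#'
#' Pairwise Pearson correlations are computed over (a sample of) the
#' non-nodata pixels of the stack — conventionally the current scenario,
#' whose retained set is then reused for all futures. While any pair exceeds
#' `threshold` in absolute value, the member of the currently worst pair with
#' the larger mean absolute correlation against all other remaining variables
#' is dropped (tie: the variable later in canonical table order goes).
#' Zero-variance layers are dropped first with a warning.
#'
#' @param stack A `climate_stack`.
#' @param sample_pixels Number of pixels used for the correlations; all
#'   usable pixels when `Inf` (default) or when fewer are available.
#' @param threshold Absolute-correlation bound (default 0.85).
#' @param seed Integer seed for the pixel sample (unused when all pixels fit).
#' @return List with `retained` (codes, canonical order), `dropped`
#'   (data.frame: variable, reason, partner, r) and `correlations` (matrix
#'   over the screened variables).
#' @export
screen_collinearity <- function(stack, sample_pixels = Inf, threshold = 0.85,
                                seed = 1L) {
  stopifnot(inherits(stack, "climate_stack"))
  vars <- stack_variables(stack)
  if (length(vars) < 2) stop("need at least two variables to screen")
  ok <- usable_mask(stack$grid) & !Reduce(`|`, lapply(stack$layers, is.na))
  pix <- which(ok)
  if (is.finite(sample_pixels) && sample_pixels < length(pix)) {
    pix <- with_seed(child_seed(seed, 6L), sample(pix, sample_pixels))
  }
  vals <- vapply(vars, function(v) stack$layers[[v]][pix],
                 numeric(length(pix)))
  dropped <- data.frame(variable = character(0), reason = character(0),
                        partner = character(0), r = numeric(0),
                        stringsAsFactors = FALSE)
  sds <- apply(vals, 2, stats::sd)
  if (any(sds == 0)) {
    for (v in vars[sds == 0]) {
      warning("constant layer dropped before screening: ", v)
      dropped <- rbind(dropped, data.frame(variable = v,
                                           reason = "zero_variance",
                                           partner = NA_character_,
                                           r = NA_real_))
    }
    vars <- vars[sds > 0]
    vals <- vals[, vars, drop = FALSE]
  }
  cm <- stats::cor(vals)
  keep <- vars
  repeat {
    if (length(keep) < 2) break
    sub <- abs(cm[keep, keep, drop = FALSE])
    diag(sub) <- 0
    if (max(sub) <= threshold) break
    worst <- which(sub == max(sub), arr.ind = TRUE)[1L, ]
    pair <- c(keep[worst[1L]], keep[worst[2L]])
    mean_abs <- vapply(pair, function(v) {
      others <- setdiff(keep, v)
      mean(abs(cm[v, others]))
    }, numeric(1))
    # tie -> drop the member later in canonical table order
    drop_v <- if (mean_abs[1L] > mean_abs[2L]) pair[1L]
              else if (mean_abs[2L] > mean_abs[1L]) pair[2L]
              else pair[which.max(match(pair, bio_variables))]
    partner <- setdiff(pair, drop_v)
    dropped <- rbind(dropped, data.frame(variable = drop_v,
                                         reason = "collinear",
                                         partner = partner,
                                         r = cm[drop_v, partner]))
    keep <- setdiff(keep, drop_v)
  }
  list(retained = intersect(bio_variables, keep), dropped = dropped,
       correlations = cm)
}

#' Pixel-wise mean of climate stacks across models
#'
#' Averages co-registered stacks (e.g. the same future scenario from several
#' climate models) per pixel and per variable. A pixel is nodata in the
#' ensemble if it is nodata in any member.
#'
#' @param stacks Non-empty list of `climate_stack`s sharing grid, scenario
#'   and variable set.
#' @return A `climate_stack` with `gcm = "ensemble"`.
#' @export
ensemble_mean <- function(stacks) {
  if (!length(stacks)) stop("empty stack list")
  stopifnot(all(vapply(stacks, inherits, logical(1), "climate_stack")))
  g <- stacks[[1L]]$grid
  vars <- stack_variables(stacks[[1L]])
  for (s in stacks[-1L]) {
    if (!same_grid(g, s$grid)) stop("stacks are not co-registered")
    if (!identical(stack_variables(s), vars)) stop("variable sets differ")
    if (!identical(s$scenario, stacks[[1L]]$scenario)) {
      stop("scenario labels differ")
    }
  }
  layers <- lapply(vars, function(v) {
    Reduce(`+`, lapply(stacks, function(s) s$layers[[v]])) / length(stacks)
  })
  names(layers) <- vars
  new_climate_stack(g, layers, scenario = stacks[[1L]]$scenario,
                    gcm = "ensemble")
}

#' Extract climate values at point locations
#'
#' Returns the containing pixel's value for every variable. Points outside
#' the grid extent, or on nodata pixels, yield `NA` rows and are flagged in
#' the `"excluded"` attribute so downstream stages can drop them.
#'
#' @param points Data.frame (or matrix) with columns `lon`, `lat`.
#' @param stack A `climate_stack`.
#' @return Numeric matrix (points x variables) with Bio-code column names;
#'   attribute `"excluded"` is a logical vector.
#' @export
extract_values <- function(points, stack) {
  stopifnot(inherits(stack, "climate_stack"))
  points <- as.data.frame(points)
  stopifnot(all(c("lon", "lat") %in% names(points)))
  idx <- cell_index(stack$grid, points$lon, points$lat)
  lin <- (idx$col - 1L) * stack$grid$n_rows + idx$row
  vars <- stack_variables(stack)
  out <- vapply(vars, function(v) stack$layers[[v]][lin],
                numeric(nrow(points)))
  if (nrow(points) == 1L) out <- matrix(out, nrow = 1L,
                                        dimnames = list(NULL, vars))
  excluded <- is.na(lin) | apply(is.na(out), 1, any)
  attr(out, "excluded") <- excluded
  out
}
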