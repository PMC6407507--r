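#' @title Model evaluation and retention
#' @description Rank-based AUC against the background sample, the six
#'   presence thresholds, training omission rates, and the retention rule
#'   (mean AUC > 0.7 and mean training omission < 0.017).
#' @name evaluation
NULL

#' Rank-based AUC of presence vs background scores
#'
#' The probability that a randomly chosen presence outranks a randomly
#' chosen background point, with ties counting one half — equivalently the
#' area under the ROC curve treating every score as a candidate threshold.
#' Invariant under strictly monotone transforms of the scores.
#'
#' @param scores_presence,scores_background Non-empty numeric vectors.
#' @return AUC in `[0, 1]`; 0.5 when all scores are identical.
#' @export
compute_auc <- function(scores_presence, scores_background) {
  m <- length(scores_presence); n <- length(scores_background)
  stopifnot(m >= 1, n >= 1)
  r <- rank(c(scores_presence, scores_background))
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' Derive the six presence thresholds
#'
#' All thresholds are expressed on the raw (Gibbs density) scale of the
#' model: fixed cumulative values 5 and 10 (the smallest background raw
#' value whose cumulative output reaches the target); the score where
#' training sensitivity equals specificity; the scores maximising training
#' and test sensitivity + specificity; and the raw value at which a
#' uniform-above-threshold distribution over the background has the same
#' entropy as the fitted distribution (the `round(exp(H))`-th largest
#' background raw value).
#'
#' @param model A `maxent_model`.
#' @param train_scores Raw scores of the training presences.
#' @param test_scores Raw scores of the test presences; when `NULL` the
#'   test-based rule is `NA` with a warning.
#' @return Named numeric vector: `cumulative_5`, `cumulative_10`,
#'   `equal_train_sens_spec`, `max_train_sens_spec`, `max_test_sens_spec`,
#'   `equal_entropy`.
#' @export
derive_thresholds <- function(model, train_scores, test_scores = NULL) {
  stopifnot(inherits(model, "maxent_model"))
  bg <- model$bg_raw
  srt <- sort(bg)
  cum <- 100 * cumsum(srt)
  cum_threshold <- function(target) srt[which(cum >= target)[1L]]
  sens_spec_threshold <- function(pres, objective) {
    cand <- sort(unique(c(pres, bg)))
    sens <- vapply(cand, function(t) mean(pres >= t), numeric(1))
    spec <- vapply(cand, function(t) mean(bg < t), numeric(1))
    crit <- objective(sens, spec)
    cand[which(crit == max(crit))[1L]]
  }
  eq_ss <- sens_spec_threshold(train_scores,
                               function(s, p) -abs(s - p))
  max_train <- sens_spec_threshold(train_scores, function(s, p) s + p)
  max_test <- if (is.null(test_scores)) {
    warning("no test scores; max test sens+spec threshold is NA")
    NA_real_
  } else {
    sens_spec_threshold(test_scores, function(s, p) s + p)
  }
  n_above <- min(max(round(exp(model$H)), 1L), length(bg))
  eq_entropy <- sort(bg, decreasing = TRUE)[n_above]
  c(cumulative_5 = cum_threshold(5), cumulative_10 = cum_threshold(10),
    equal_train_sens_spec = eq_ss, max_train_sens_spec = max_train,
    max_test_sens_spec = max_test, equal_entropy = eq_entropy)
}

#' Omission rate of presences at a threshold
#'
#' Fraction of presence scores strictly below the threshold; ties are
#' counted as predicted present.
#'
#' @param train_presence_scores Numeric vector on the threshold's scale.
#' @param threshold Single numeric threshold.
#' @return Omission rate in `[0, 1]`.
#' @export
omission_rate <- function(train_presence_scores, threshold) {
  if (is.na(threshold)) return(NA_real_)
  mean(train_presence_scores < threshold)
}

#' Evaluate a cross-validated model
#'
#' Per fold: AUC of the held-out (test) presences against the background,
#' and the training omission rate under each of the six thresholds (mean
#' over rules within the fold). Summaries are means over folds. Scoring is
#' on the raw scale; AUC is scale-invariant, and thresholds are derived on
#' the raw scale.
#'
#' @param cv An `sdm_cv` from [cross_validate()].
#' @param auc_min,omission_max Retention bounds (defaults 0.7 / 0.017).
#' @return An `evaluation_report`: `folds` data.frame (fold, auc,
#'   omission_* columns, mean_omission), `mean_auc`, `mean_omission`,
#'   `retained`.
#' @export
evaluate_sdm <- function(cv, auc_min = 0.7, omission_max = 0.017) {
  stopifnot(inherits(cv, "sdm_cv"))
  rule_names <- c("cumulative_5", "cumulative_10", "equal_train_sens_spec",
                  "max_train_sens_spec", "max_test_sens_spec",
                  "equal_entropy")
  rows <- lapply(seq_len(cv$k), function(j) {
    mod <- cv$models[[j]]
    tr <- cv$folds != j
    train_raw <- score_values(mod, cv$presence_values[tr, , drop = FALSE],
                              "raw")
    test_raw <- score_values(mod, cv$presence_values[!tr, , drop = FALSE],
                             "raw")
    th <- derive_thresholds(mod, train_raw, test_raw)
    om <- vapply(th, omission_rate, numeric(1),
                 train_presence_scores = train_raw)
    auc <- compute_auc(test_raw, mod$bg_raw)
    out <- data.frame(fold = j, auc = auc)
    for (r in rule_names) out[[paste0("omission_", r)]] <- om[[r]]
    out$mean_omission <- mean(om, na.rm = TRUE)
    out
  })
  folds <- do.call(rbind, rows)
  mean_auc <- mean(folds$auc)
  mean_omission <- mean(folds$mean_omission)
  structure(list(folds = folds, mean_auc = mean_auc,
                 mean_omission = mean_omission,
                 retained = retain(mean_auc, mean_omission,
                                   auc_min, omission_max),
                 auc_min = auc_min, omission_max = omission_max),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> mean AUC %.3f, mean omission %.4f -> %s\n",
              x$mean_auc, x$mean_omission,
              if (x$retained) "retained" else "dropped"))
  invisible(x)
}

#' Retention rule
#'
#' A species' model enters the downstream analysis only if mean AUC exceeds
#' `auc_min` and mean training omission is below `omission_max`.
#'
#' @param auc Mean AUC.
#' @param omission Mean training omission rate.
#' @param auc_min,omission_max Bounds (defaults 0.7 / 0.017).
#' @return Logical.
#' @export
retain <- function(auc, omission, auc_min = 0.7, omission_max = 0.017) {
  isTRUE(auc > auc_min && omission < omission_max)
}
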