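.ensemble_channels <- c("p_vj", "p_len", "p_shm", "p_seq")

#' Fit the boosted linear ensemble over the four channel probabilities
#'
#' Combines the per-sequence tumor probabilities of the four
#' feature-specific classifiers (`p_vj`, `p_len`, `p_shm`, `p_seq`) with a
#' linear gradient-boosted machine (xgboost, `booster = "gblinear"`,
#' logistic objective). Boosting hyperparameters are left at the
#' implementation defaults; a single thread is used for determinism.
#'
#' @param probs tibble/data frame with the four channel columns and a
#'   `label` column (`"normal"`/`"tumor"`).
#' @param nrounds boosting rounds (default 100, the usual implementation
#'   default).
#' @return an `ensemble_model` with a `coefficients` vector (intercept +
#'   one weight per channel).
#' @export
fit_ensemble <- function(probs, nrounds = 100) {
  missing <- setdiff(.ensemble_channels, names(probs))
  .assert(length(missing) == 0,
          paste0("missing channel(s): ", paste(missing, collapse = ", ")))
  y <- .label01(probs$label)
  x <- as.matrix(probs[, .ensemble_channels])
  bst <- xgboost::xgb.train(
    params = list(booster = "gblinear", objective = "binary:logistic",
                  nthread = 1),
    data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
    nrounds = nrounds, verbose = 0
  )
  w <- stats::coef(bst)[-1]
  # effective intercept on the margin scale (includes the global base score)
  margin <- stats::predict(bst, xgboost::xgb.DMatrix(x, nthread = 1),
                           outputmargin = TRUE)
  intercept <- mean(margin - as.numeric(x %*% w))
  coefs <- stats::setNames(c(intercept, w), c("intercept", .ensemble_channels))
  structure(list(booster = bst, coefficients = coefs), class = "ensemble_model")
}

#' Predict per-sequence tumor probability from the ensemble
#' @param model an `ensemble_model`.
#' @param probs data frame with the four channel columns.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict_ensemble <- function(model, probs) {
  x <- as.matrix(probs[, .ensemble_channels])
  as.numeric(stats::predict(model$booster, xgboost::xgb.DMatrix(x, nthread = 1)))
}

#' Aggregate per-sequence probabilities into a tissue-level score
#'
#' The tissue score of a sample is a descriptive statistic of the tumor
#' probabilities of all its sequences: the arithmetic mean (the primary
#' statistic), the median, or the mode — defined for a continuous score as
#' the midpoint of the fullest bin of a fixed-width histogram on `[0, 1]`
#' (ties broken toward the lowest midpoint).
#'
#' @param p numeric vector of per-sequence tumor probabilities (non-empty).
#' @param statistic `"mean"`, `"median"` or `"mode"`.
#' @param bin_width histogram bin width for the mode (default 0.02).
#' @return a single score in `[0, 1]`.
#' @export
tissue_score <- function(p, statistic = c("mean", "median", "mode"),
                         bin_width = 0.02) {
  statistic <- match.arg(statistic)
  .assert(length(p) >= 1, "empty probability list")
  switch(statistic,
    mean = mean(p),
    median = stats::median(p),
    mode = {
      breaks <- seq(0, 1, by = bin_width)
      if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
      bin <- findInterval(p, breaks, rightmost.closed = TRUE)
      counts <- tabulate(bin, nbins = length(breaks) - 1)
      b <- which.max(counts)   # which.max takes the lowest maximal bin
      (breaks[b] + breaks[b + 1]) / 2
    }
  )
}

#' Score every tissue sample of a cohort
#'
#' Groups per-sequence probabilities by patient and tissue and applies
#' [tissue_score()]. Each unique sequence counts once by default;
#' `weight_by_reads = TRUE` repeats each probability by its
#' `duplicate_count` instead.
#'
#' @param records repertoire records (all sequences of each sample, not
#'   only specific-clone members).
#' @param p per-sequence tumor probabilities aligned with `records`.
#' @param statistic,bin_width passed to [tissue_score()].
#' @param weight_by_reads read-weighted aggregation (default FALSE).
#' @return tibble `patient_id`, `tissue`, `statistic`, `score`,
#'   `n_sequences`.
#' @export
score_tissue_samples <- function(records, p,
                                 statistic = c("mean", "median", "mode"),
                                 bin_width = 0.02, weight_by_reads = FALSE) {
  statistic <- match.arg(statistic)
  records$.p <- p
  records %>%
    dplyr::group_by(.data$patient_id, .data$tissue) %>%
    dplyr::summarise(
      statistic = statistic,
      score = {
        pp <- if (weight_by_reads) rep(.data$.p, .data$duplicate_count) else .data$.p
        tissue_score(pp, statistic, bin_width)
      },
      n_sequences = dplyr::n(),
      .groups = "drop"
    )
}

#' Tissue-level classification with a clonal-entropy channel
#'
#' Compares tissue-level classification with and without the clonal
#' entropy of each sample as an extra input. Without entropy the sample
#' score itself is the classifier (its AUC is transform-invariant); with
#' entropy, a boosted linear model on `(score, entropy)` re-scores the
#' samples through the same machinery as the sequence-level ensemble. The
#' comparison asks whether the entropy channel carries additional
#' class signal; a constant entropy channel leaves the ranking, and hence
#' the AUC, unchanged.
#'
#' @param samples tibble with columns `patient_id`, `tissue` (the true
#'   label), `score` and `entropy`.
#' @param nrounds boosting rounds.
#' @return list with `auc_without`, `auc_with`, and the per-sample
#'   augmented predictions.
#' @export
augment_with_entropy <- function(samples, nrounds = 100) {
  y <- .label01(samples$tissue)
  auc_without <- .auc01(samples$score, y)
  x <- as.matrix(samples[, c("score", "entropy")])
  bst <- xgboost::xgb.train(
    params = list(booster = "gblinear", objective = "binary:logistic",
                  nthread = 1),
    data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
    nrounds = nrounds, verbose = 0
  )
  pred <- as.numeric(stats::predict(bst, xgboost::xgb.DMatrix(x, nthread = 1)))
  list(auc_without = auc_without, auc_with = .auc01(pred, y),
       augmented = dplyr::mutate(samples, p_augmented = pred))
}
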