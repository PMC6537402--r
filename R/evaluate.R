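#' ROC curve and AUC
#'
#' The AUC is the Mann-Whitney statistic: the fraction of
#' (positive, negative) pairs ranked concordantly, ties counted half.
#' Curve points are computed at every distinct score threshold, no
#' interpolation.
#'
#' @param scores numeric scores (larger = more tumor-like).
#' @param labels `"normal"`/`"tumor"` labels; both classes must be present.
#' @return a `roc_result` list: `auc`, `curve` (tibble `fpr`, `tpr`,
#'   starting at (0,0) and ending at (1,1)), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  y <- .label01(labels)
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  .assert(n_pos > 0 && n_neg > 0, "both classes must be present")
  auc <- .auc01(scores, y)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  keep <- c(ss[-length(ss)] != ss[-1], TRUE)  # last index of each distinct score
  tpr <- cumsum(ys == 1L)[keep] / n_pos
  fpr <- cumsum(ys == 0L)[keep] / n_neg
  structure(list(
    auc = auc,
    curve = tibble(fpr = c(0, fpr), tpr = c(0, tpr)),
    n_pos = n_pos, n_neg = n_neg
  ), class = "roc_result")
}

#' Within-patient permutation test of a per-sequence classifier
#'
#' Tests whether the average per-patient AUC exceeds chance. In each
#' permutation the sequence labels are shuffled independently within each
#' patient (so every patient's label multiset is preserved) and the average
#' per-patient AUC recomputed; held-out patients whose label set is
#' degenerate (fewer than one sequence of either class) are skipped and
#' logged. The p-value uses the add-one estimator
#' `p = (1 + #permuted >= observed) / (1 + n_permutations)`.
#'
#' @param predictions tibble with `patient_id`, `p` (score) and `label`.
#' @param n_permutations number of permutations (default 1000; the
#'   full-scale analysis uses 1e5).
#' @param seed integer seed.
#' @return list with `p_value`, `observed` (mean per-patient AUC) and
#'   `permuted` (vector of permuted statistics).
#' @export
permutation_test <- function(predictions, n_permutations = 1000, seed = 1) {
  .assert(n_permutations >= 1, "n_permutations must be >= 1")
  withr::local_seed(.subseed(seed, 13))
  by_pat <- split(predictions[, c("p", "label")], predictions$patient_id)
  y_by_pat <- lapply(by_pat, function(d) .label01(d$label))
  usable <- vapply(y_by_pat, function(y) min(sum(y == 1), sum(y == 0)) >= 1,
                   logical(1))
  if (any(!usable)) {
    message(sum(!usable), " patient(s) skipped: single-class label set")
  }
  .assert(any(usable), "no patient with both classes present")
  by_pat <- by_pat[usable]; y_by_pat <- y_by_pat[usable]
  stat <- function(ys) {
    mean(mapply(function(d, y) .auc01(d$p, y), by_pat, ys))
  }
  observed <- stat(y_by_pat)
  permuted <- vapply(seq_len(n_permutations), function(b) {
    stat(lapply(y_by_pat, sample))
  }, numeric(1))
  list(
    p_value = (1 + sum(permuted >= observed)) / (1 + n_permutations),
    observed = observed,
    permuted = permuted
  )
}

#' Paired comparison of two classifiers' per-patient AUCs
#'
#' Two-sided Wilcoxon signed-rank test on the paired per-patient AUC
#' differences, with a Bonferroni adjustment for `n_comparisons` tests.
#' Zero differences are dropped (classic signed-rank handling); if every
#' difference is zero the p-value is 1.
#'
#' @param auc_a,auc_b equal-length (>= 6) per-patient AUC vectors, paired
#'   by patient.
#' @param n_comparisons Bonferroni multiplier (default 1).
#' @return list with `p_value` (adjusted, clamped at 1), `p_raw` and
#'   `n_used` (pairs with nonzero difference).
#' @export
compare_paired_auc <- function(auc_a, auc_b, n_comparisons = 1) {
  .assert(length(auc_a) == length(auc_b), "AUC lists must have equal length")
  .assert(length(auc_a) >= 6, "need at least 6 paired patients")
  d <- auc_a - auc_b
  d <- d[!is.na(d)]
  nz <- d[d != 0]
  if (length(nz) == 0) {
    return(list(p_value = 1, p_raw = 1, n_used = 0L))
  }
  p_raw <- suppressWarnings(
    stats::wilcox.test(nz, alternative = "two.sided")$p.value
  )
  list(p_value = min(1, p_raw * n_comparisons), p_raw = p_raw,
       n_used = length(nz))
}

#' Per-position residue frequencies of confidently classified CDRs
#'
#' Builds the frequency matrix behind a sequence-logo view of one
#' confidence group: sequences whose true and predicted labels place them
#' in `group`, predicted with probability above `confidence`. Only
#' sequences whose region has the modal length (8/8/17 for CDR1/2/3) are
#' used, and for CDR3 the conserved ends (positions 1-3 and the last 4)
#' are removed, leaving 10 positions. Sequences containing `X` in the
#' region are excluded so columns are frequencies over the 20 residues.
#'
#' @param records repertoire records with true labels in `label`.
#' @param p per-sequence tumor probabilities aligned with `records`.
#' @param region `"CDR1"`, `"CDR2"` or `"CDR3"`.
#' @param group `"correct-normal"`, `"correct-tumor"`, `"miscalled-tumor"`
#'   (true normal predicted tumor) or `"miscalled-normal"`.
#' @param confidence probability threshold (default 0.9).
#' @param targets modal region lengths.
#' @return a `motif_matrix`: positions x 20 matrix of residue frequencies
#'   (each row sums to 1), with attributes `region`, `group` and `n`.
#' @export
motif_frequency_matrix <- function(records, p, region = c("CDR3", "CDR1", "CDR2"),
                                   group = c("correct-normal", "correct-tumor",
                                             "miscalled-tumor", "miscalled-normal"),
                                   confidence = 0.9,
                                   targets = c(CDR1 = 8, CDR2 = 8, CDR3 = 17)) {
  region <- match.arg(region)
  group <- match.arg(group)
  true_tumor <- records$label == "tumor"
  sel <- switch(group,
    "correct-normal" = !true_tumor & (1 - p) > confidence,
    "correct-tumor" = true_tumor & p > confidence,
    "miscalled-tumor" = !true_tumor & p > confidence,
    "miscalled-normal" = true_tumor & (1 - p) > confidence
  )
  col <- c(CDR1 = "cdr1_aa", CDR2 = "cdr2_aa", CDR3 = "cdr3_aa")[region]
  seqs <- records[[col]][sel]
  seqs <- seqs[nchar(seqs) == targets[region] & !grepl("X", seqs)]
  if (length(seqs) == 0) {
    census <- table(factor(
      ifelse(true_tumor, ifelse(p > confidence, "correct-tumor",
                                ifelse(1 - p > confidence, "miscalled-normal", "low-confidence")),
             ifelse(1 - p > confidence, "correct-normal",
                    ifelse(p > confidence, "miscalled-tumor", "low-confidence")))))
    rlang::abort(paste0(
      "no sequences in group '", group, "' for ", region,
      "; group census: ",
      paste(names(census), census, sep = "=", collapse = ", ")
    ))
  }
  mat <- do.call(rbind, strsplit(seqs, ""))
  if (region == "CDR3") {
    mat <- mat[, 4:(ncol(mat) - 4), drop = FALSE]
  }
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  freq <- t(apply(mat, 2, function(colv) {
    tab <- table(factor(colv, levels = aa20))
    as.numeric(tab) / length(colv)
  }))
  colnames(freq) <- aa20
  rownames(freq) <- paste0("pos", seq_len(nrow(freq)) +
                             if (region == "CDR3") 3L else 0L)
  structure(freq, class = c("motif_matrix", "matrix"),
            region = region, group = group, n = length(seqs))
}
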