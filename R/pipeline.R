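#' Build the labeled training pool of a cohort
#'
#' Per patient: assign clonal families, extract dominant tissue-specific
#' clones, and sample `k` sequences per clone. Patients with no
#' tumor-specific or no normal-specific clone cannot contribute balanced
#' training data and are dropped with a message.
#'
#' @param cohort repertoire records of several patients.
#' @param min_reads,purity_threshold passed to
#'   [extract_dominant_clones()].
#' @param k sequences sampled per clone.
#' @param seed integer seed.
#' @return labeled training records (`label` column), plus a
#'   `families` attribute holding each patient's full family table.
#' @export
prepare_training_cohort <- function(cohort, min_reads = 50,
                                    purity_threshold = 0.9, k = 3, seed = 1) {
  pats <- unique(cohort$patient_id)
  fam_list <- list()
  out <- list()
  for (i in seq_along(pats)) {
    p <- pats[i]
    fams <- assign_clonal_families(cohort[cohort$patient_id == p, ])
    fam_list[[p]] <- fams
    dom <- extract_dominant_clones(fams, min_reads, purity_threshold)
    if (length(unique(dom$specific_label)) < 2) {
      message("patient ", p, " dropped from training: no ",
              setdiff(c("normal", "tumor"), unique(dom$specific_label)),
              "-specific clones")
      next
    }
    out[[p]] <- sample_training_sequences(dom, k, .subseed(seed, 30 + i))
  }
  .assert(length(out) > 0, "no patient with both clone classes")
  res <- dplyr::bind_rows(out)
  attr(res, "families") <- fam_list
  res
}

#' Fit the four per-sequence channel models
#'
#' @param train labeled training records.
#' @param seed integer seed.
#' @param seq_algorithm,seq_budget,seq_epochs configuration of the
#'   CDR-sequence channel (see [fit_sequence_classifier()]).
#' @return a `channel_models` list with fields `vj`, `len`, `shm`, `seq`.
#' @export
fit_channel_models <- function(train, seed = 1, seq_algorithm = "convnet",
                               seq_budget = 10, seq_epochs = 30) {
  sseq <- spec_seq(seq_algorithm, budget = seq_budget, epochs = seq_epochs)
  structure(list(
    vj = fit_patient_averaged_bayes(train, "vj_frame"),
    len = fit_patient_averaged_bayes(train, "cdr_length"),
    shm = fit_shm_classifier(train, train$label),
    seq = sseq$fit(train, .subseed(seed, 40)),
    seq_spec = sseq
  ), class = "channel_models")
}

#' Channel probabilities of a set of records
#' @param models a `channel_models` list.
#' @param records records to score.
#' @return tibble with `sequence_id`, `p_vj`, `p_len`, `p_shm`, `p_seq`.
#' @export
channel_probabilities <- function(models, records) {
  tibble(
    sequence_id = records$sequence_id,
    p_vj = predict_bayes(models$vj, records),
    p_len = predict_bayes(models$len, records),
    p_shm = predict_shm(models$shm, records),
    p_seq = models$seq_spec$predict(models$seq, records)
  )
}

#' Out-of-fold channel probabilities for ensemble stacking
#'
#' In-sample channel probabilities overstate the skill of flexible models
#' (a forest scores its own training data almost perfectly), which would
#' mislead the ensemble's weights. This produces honest training
#' probabilities by a two-fold patient-level split: each half is scored by
#' channel models fitted on the other half.
#'
#' @param train labeled training records (>= 2 patients).
#' @param seed integer seed.
#' @inheritParams fit_channel_models
#' @return tibble of channel probabilities aligned with `train`, plus the
#'   `label` column.
#' @export
oof_channel_probabilities <- function(train, seed = 1,
                                      seq_algorithm = "convnet",
                                      seq_budget = 10, seq_epochs = 30) {
  fold <- .two_fold_split(train$patient_id, .subseed(seed, 61))
  out <- vector("list", 2)
  for (f in 1:2) {
    fit_on <- train[fold != f, , drop = FALSE]
    score_on <- train[fold == f, , drop = FALSE]
    m <- fit_channel_models(fit_on, .subseed(seed, 70 + f),
                            seq_algorithm, seq_budget, seq_epochs)
    pr <- channel_probabilities(m, score_on)
    pr$label <- score_on$label
    out[[f]] <- pr
  }
  res <- dplyr::bind_rows(out)
  res[match(train$sequence_id, res$sequence_id), ]
}

#' Leave-one-patient-out evaluation of the full pipeline
#'
#' For each held-out patient: the four channel models and the ensemble are
#' trained on the other patients' clone-sampled training sequences (the
#' ensemble is stacked on the channels' training-set probabilities), then
#' every sequence of the held-out patient's two samples — all sequences,
#' not only specific-clone members — is scored, and each sample is
#' aggregated to tissue scores with the mean, median and mode statistics.
#' Per-sample clonal entropy (base-2, on the sample's per-clone read
#' counts) is attached for the entropy-augmentation comparison.
#'
#' @param cohort raw simulated or observed cohort records.
#' @param seed integer seed.
#' @param min_reads,purity_threshold,k training-pool construction.
#' @param seq_algorithm,seq_budget,seq_epochs CDR-sequence channel setup.
#' @return list: `sequence_oof` (held-out per-sequence channel + ensemble
#'   probabilities with the tissue of origin as label), `samples` (one row
#'   per patient x tissue x statistic with `score`, `entropy`,
#'   `n_sequences`), `per_patient_auc` (held-out ensemble AUC per patient
#'   over its labeled sequences).
#' @export
evaluate_cohort_loocv <- function(cohort, seed = 1, min_reads = 50,
                                  purity_threshold = 0.9, k = 3,
                                  seq_algorithm = "convnet", seq_budget = 10,
                                  seq_epochs = 30) {
  train_pool <- prepare_training_cohort(cohort, min_reads, purity_threshold,
                                        k, seed)
  fam_list <- attr(train_pool, "families")
  pats <- unique(cohort$patient_id)
  oof <- list(); samples <- list(); pp_auc <- list()
  for (i in seq_along(pats)) {
    p <- pats[i]
    tr <- train_pool[train_pool$patient_id != p, , drop = FALSE]
    if (length(unique(tr$label)) < 2) next
    models <- fit_channel_models(tr, .subseed(seed, 50 + i),
                                 seq_algorithm, seq_budget, seq_epochs)
    tr_probs <- oof_channel_probabilities(tr, .subseed(seed, 50 + i),
                                          seq_algorithm, seq_budget, seq_epochs)
    ens <- fit_ensemble(tr_probs)
    te <- cohort[cohort$patient_id == p, , drop = FALSE]
    te_probs <- channel_probabilities(models, te)
    te_probs$p_ensemble <- predict_ensemble(ens, te_probs)
    te_probs$patient_id <- p
    te_probs$label <- te$tissue    # tissue of origin = per-sequence label
    oof[[p]] <- te_probs
    y <- .label01(te_probs$label)
    pp_auc[[p]] <- tibble(patient_id = p,
                          auc = .auc01(te_probs$p_ensemble, y),
                          n = nrow(te))
    fams <- fam_list[[p]]
    ent <- te %>%
      dplyr::group_by(.data$tissue, .data$clone_id) %>%
      dplyr::summarise(reads = sum(.data$duplicate_count), .groups = "drop_last") %>%
      dplyr::summarise(entropy = clonal_entropy(.data$reads), .groups = "drop")
    for (st in c("mean", "median", "mode")) {
      sc <- score_tissue_samples(te, te_probs$p_ensemble, st)
      sc <- dplyr::left_join(sc, ent, by = "tissue")
      samples[[paste(p, st)]] <- sc
    }
  }
  list(
    sequence_oof = dplyr::bind_rows(oof),
    samples = dplyr::bind_rows(samples),
    per_patient_auc = dplyr::bind_rows(pp_auc)
  )
}
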