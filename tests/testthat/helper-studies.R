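# shared study evaluations, computed once per test run and cached

.study_cache <- new.env(parent = emptyenv())

# default-study channel models + ensemble + iid test scores
default_study_eval <- function() {
  if (!is.null(.study_cache$default)) return(.study_cache$default)
  cfg <- bcrclassify::study_config("default", seed = 3)
  co <- bcrclassify::simulate_cohort(cfg)
  tr <- suppressMessages(bcrclassify::prepare_training_cohort(co, seed = 3))
  models <- bcrclassify::fit_channel_models(tr, seed = 3, seq_algorithm = "forest")
  tr_oof <- bcrclassify::oof_channel_probabilities(tr, seed = 3,
                                                   seq_algorithm = "forest")
  ens <- bcrclassify::fit_ensemble(tr_oof)
  te <- bcrclassify::simulate_sequences(cfg, 2000, seed = 303)
  pr <- bcrclassify::channel_probabilities(models, te)
  pr$p_ensemble <- bcrclassify::predict_ensemble(ens, pr)
  .study_cache$default <- list(cfg = cfg, models = models, ensemble = ens,
                               test = te, probs = pr)
  .study_cache$default
}

# tissue-level scores over fresh evaluation patients at a given sample size
tissue_eval <- function(n_per_sample, n_eval_patients = 30, seed_base = 400) {
  ev <- default_study_eval()
  out <- list()
  for (ep in seq_len(n_eval_patients)) {
    tep <- bcrclassify::simulate_sequences(
      ev$cfg, n_per_sample, patient_id = sprintf("E%02d", ep),
      seed = seed_base + ep)
    prp <- bcrclassify::channel_probabilities(ev$models, tep)
    pep <- bcrclassify::predict_ensemble(ev$ensemble, prp)
    for (tis in c("normal", "tumor")) {
      sel <- tep$tissue == tis
      out[[paste(ep, tis)]] <- tibble::tibble(
        tissue = tis,
        mean = bcrclassify::tissue_score(pep[sel], "mean"),
        median = bcrclassify::tissue_score(pep[sel], "median"),
        mode = bcrclassify::tissue_score(pep[sel], "mode")
      )
    }
  }
  dplyr::bind_rows(out)
}
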