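#!/usr/bin/env Rscript
# Per-sequence classification of the default cohort: patient-level
# leave-one-out cross-validation of the four feature channels, plus a
# within-patient permutation test of the strongest channel.
#
# The CDR-sequence channel uses the forest model here to keep the driver
# fast; analysis/05_motif_benchmark.R compares all three sequence models.

suppressMessages({
  library(bcrclassify)
  library(dplyr)
})
dir.create("results", showWarnings = FALSE)

co <- read_repertoire("results/data/cohort_default.tsv")
train <- prepare_training_cohort(co, seed = 2)

specs <- list(
  vj = spec_bayes("vj_frame"),
  len = spec_bayes("cdr_length"),
  shm = spec_shm(),
  seq = spec_seq("forest")
)

aucs <- list(); oofs <- list()
for (nm in names(specs)) {
  res <- nested_cv(train, specs[[nm]], seed = 2)
  aucs[[nm]] <- mutate(res$per_patient, channel = nm)
  oofs[[nm]] <- mutate(res$oof, channel = nm)
  cat(sprintf("channel %-4s mean per-patient AUC %.3f\n",
              nm, mean(res$per_patient$auc, na.rm = TRUE)))
}
per_patient <- bind_rows(aucs)
readr::write_tsv(per_patient, "results/per_patient_auc.tsv")

# paired comparison of the channels, Bonferroni over the 6 pairs
wide <- tidyr::pivot_wider(per_patient[, c("patient_id", "channel", "auc")],
                           names_from = "channel", values_from = "auc")
pairs <- utils::combn(names(specs), 2, simplify = FALSE)
for (pr in pairs) {
  cmp <- compare_paired_auc(wide[[pr[1]]], wide[[pr[2]]],
                            n_comparisons = length(pairs))
  cat(sprintf("%s vs %s: adjusted p = %.4g\n", pr[1], pr[2], cmp$p_value))
}

# permutation test: does the SHM channel beat label shuffling?
shm_oof <- oofs$shm
perm <- permutation_test(
  tibble(patient_id = shm_oof$patient_id, p = shm_oof$p, label = shm_oof$label),
  n_permutations = 1000, seed = 2
)
cat(sprintf("\nSHM channel: observed mean AUC %.3f, permutation p = %.4g\n",
            perm$observed, perm$p_value))
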