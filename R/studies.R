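#' Canonical synthetic study configurations
#'
#' The calibration and benchmark studies shipped with the package each pin
#' one generator configuration:
#' \describe{
#'   \item{default}{mild effects in every channel (V/J usage, CDR3 length,
#'     SHM counts, CDR3 motif) at the default cohort size — the general
#'     demonstration cohort.}
#'   \item{vj_channel}{only a (V, J)-usage effect, on a compact 8 x 3 gene
#'     panel so the patient-averaged likelihood tables are well estimated
#'     at 10 patients x 200 clones/tissue; used to compare the fitted
#'     Bayes classifier against [bayes_optimal_auc()] and to verify the
#'     other channels stay at chance.}
#'   \item{null}{no effect in any channel; used for chance-level and
#'     permutation calibration.}
#'   \item{motif}{only a strong planted CDR3 motif (residue W at positions
#'     6, 9, 12 with probability 0.9); the benchmark for the
#'     amino-acid-sequence classifiers.}
#'   \item{entropy}{no per-sequence effect, but tumor clone sizes are more
#'     skewed (smaller power-law exponent), so per-sample clonal entropy
#'     differs between tissues.}
#' }
#'
#' @param study study name.
#' @param n_patients,clones_per_tissue cohort size (defaults 10 x 200).
#' @param seed integer seed.
#' @return an [effect_config()].
#' @export
study_config <- function(study = c("default", "vj_channel", "null", "motif",
                                   "entropy"),
                         n_patients = 10, clones_per_tissue = 200, seed = 1) {
  study <- match.arg(study)
  no_shm <- c(fr = 8, cdr = 5)
  switch(study,
    default = effect_config(n_patients = n_patients,
                            clones_per_tissue = clones_per_tissue, seed = seed),
    vj_channel = effect_config(
      n_patients = n_patients, clones_per_tissue = clones_per_tissue,
      vj_usage_normal = vj_usage_profile(8, 3, 0),
      vj_usage_tumor = vj_usage_profile(8, 3, 0.6),
      cdrlen_shift = 0, shm_normal_mean = no_shm, shm_tumor_mean = no_shm,
      aa_motif_effect = NULL, contamination_rate = 0, seed = seed
    ),
    null = effect_config(
      n_patients = n_patients, clones_per_tissue = clones_per_tissue,
      vj_shift = 0, cdrlen_shift = 0,
      shm_normal_mean = no_shm, shm_tumor_mean = no_shm,
      aa_motif_effect = NULL, contamination_rate = 0, seed = seed
    ),
    motif = effect_config(
      n_patients = n_patients, clones_per_tissue = clones_per_tissue,
      vj_shift = 0, cdrlen_shift = 0,
      shm_normal_mean = no_shm, shm_tumor_mean = no_shm,
      aa_motif_effect = list(positions = c(6, 9, 12), residue = "W",
                             prob = 0.9),
      contamination_rate = 0, seed = seed
    ),
    entropy = effect_config(
      n_patients = n_patients, clones_per_tissue = clones_per_tissue,
      vj_shift = 0, cdrlen_shift = 0,
      shm_normal_mean = no_shm, shm_tumor_mean = no_shm,
      aa_motif_effect = NULL, contamination_rate = 0,
      read_exponent_tumor = 1.05, seed = seed
    )
  )
}
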