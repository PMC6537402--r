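# bcrclassify

Can the B-cell receptor / immunoglobulin (BCR/Ig) repertoire of a tissue
sample tell you whether the tissue is tumor or normal? BCR/Igs in a tumor
microenvironment are selected against tumor-associated antigens, so their
heavy-chain sequences may differ systematically from those in adjacent
normal tissue — in V/J germline gene usage, CDR lengths, somatic
hypermutation (SHM) load, and the physicochemical composition of the CDRs.
Because BCR/Ig sequences are hyper-diverse and rarely shared between
patients, the signal must be captured statistically with supervised models
trained across patients rather than by looking for recurrent public
clones.

`bcrclassify` is an R package plus analysis workflow for this question,
aimed at immunologists and computational biologists working with annotated
Rep-Seq (immune repertoire sequencing) data. It implements:

- **Clonotyping** — single-linkage clonal families under the criteria
  *same V/J gene, same CDR3 nucleotide length, ≤ 3 CDR3 mismatches*;
  extraction of dominant tissue-specific clones (≥ 50 reads, ≥ 90%
  single-tissue read content) and clone-balanced training sampling
  (3 sequences per clone).
- **Four per-sequence classifiers** —
  patient-averaged Bayes on V/J usage and on CDR length triples, with
  likelihoods averaged with equal patient weight,
  `P(c|k) = (1/n) Σᵢ Pᵢ(c|k)`, and posteriors from Bayes' theorem;
  a linear-kernel SVM on the (SHM-in-FR, SHM-in-CDR) counts;
  and a choice of 1-D convolutional network (implemented from scratch,
  gradient-checked), RBF-kernel SVM, or random forest on the 33 × 10
  Kidera-factor encoding of CDR1/2/3 (fixed lengths 8/8/17, center
  trim/pad, 330 features).
- **A boosted linear ensemble** (xgboost `gblinear`) over the four channel
  probabilities, stacked on out-of-fold channel predictions.
- **Tissue-level classification** — a sample is scored by aggregating the
  ensemble probabilities of *all* its sequences,
  `P_tissue(T|𝒜) = (1/|𝒜|) Σ_{A∈𝒜} P_seq(T|A)`,
  with median and histogram-mode alternatives and optional clonal-entropy
  augmentation.
- **Evaluation machinery** — patient-level nested cross-validation (outer
  leave-one-patient-out, inner two-fold), Mann–Whitney ROC/AUC,
  within-patient permutation tests, paired Wilcoxon signed-rank
  comparisons with Bonferroni correction, and CDR motif frequency
  matrices.
- **A synthetic cohort generator** with planted, per-channel
  normal-vs-tumor effects (usage tilts, length shifts, SHM shifts, CDR3
  motifs, clone-size skew, cross-tissue contamination) and an exact
  analytic bound (`bayes_optimal_auc()`) for calibration studies.

Repertoires are tibbles in an AIRR-Rearrangement-style TSV dialect:
standard columns `sequence_id`, `v_call`, `j_call`, `cdr1_aa`, `cdr2_aa`,
`cdr3_aa`, `cdr3` (CDR3 nucleotides), `duplicate_count`, plus custom
columns `patient_id`, `tissue` (`normal`/`tumor`), `shm_fr`, `shm_cdr`,
`clone_id`. Unknown extra columns are preserved but ignored.

The methods vignette (`vignettes/repertoire-classification.Rmd`) documents
the models, every tunable parameter, the generator's assumptions, and what
the synthetic studies do and do not demonstrate.

## Worked example

```r
library(bcrclassify)

# a 10-patient cohort with mild tumor effects in every feature channel
cfg <- study_config("default", seed = 3)
cohort <- simulate_cohort(cfg)
nrow(cohort)
#> [1] 6829

# clonotype one patient, extract dominant tissue-specific clones
fams <- assign_clonal_families(subset(cohort, patient_id == "P01"))
dom <- extract_dominant_clones(fams, min_reads = 50, purity_threshold = 0.9)
nrow(fams); nrow(dom); table(dom$specific_label)
#> [1] 400
#> [1] 77
#> normal  tumor
#>     35     42

# clone-balanced training pool across patients
train <- prepare_training_cohort(cohort, seed = 3)
table(train$label)
#> normal  tumor
#>    628    669

# fit the SHM channel and score held-out sequences
m_shm <- fit_shm_classifier(train, train$label)
test <- simulate_sequences(cfg, 2000, seed = 303)
roc_auc(predict_shm(m_shm, test), test$tissue)$auc
#> [1] 0.9254499
```

The 400 clonal families of patient P01 yield 77 dominant clones that are
at least 90% single-tissue by read content; sampling 3 sequences from each
dominant clone across all patients gives a near-balanced training pool.
The SHM channel alone separates held-out tumor from normal sequences with
AUC ≈ 0.93 because the default cohort plants lower SHM counts in tumor
clones (less affinity maturation); on a null cohort with no planted
effects the same classifier sits at AUC ≈ 0.5.

The numbered scripts under `analysis/` run the full studies in order —
cohort generation, clonal structure, per-sequence channel cross-validation
with permutation testing, ensemble and tissue-level evaluation, and the
CDR-sequence model benchmark with motif matrices — writing their tables
under `results/`.

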