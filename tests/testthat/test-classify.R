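make_labeled <- function(patient_id, label, v_call, n = length(v_call)) {
  r <- make_records(n, patient_id = patient_id, v_call = v_call)
  r$label <- rep_len(label, n)
  r$sequence_id <- paste0(patient_id, "_", label, "_", seq_len(n))
  r
}

test_that("likelihoods are equal-weight patient averages, not pooled counts", {
  # patient 1: category A has normal frequency 1.0; patient 2: 0.5
  tr <- dplyr::bind_rows(
    make_labeled("P01", "normal", c("A", "A")),
    make_labeled("P02", "normal", c("A", "B")),
    make_labeled("P01", "tumor", c("B", "B")),
    make_labeled("P02", "tumor", c("B", "B"))
  )
  m <- fit_patient_averaged_bayes(tr, "vj_frame")
  expect_equal(unname(m$likelihood_normal["A|IGHJ1"]), 0.75)
  expect_equal(sum(m$likelihood_normal), 1)
  expect_equal(sum(m$likelihood_tumor), 1)

  # unbalanced patients: averaging must differ from pooling
  tr2 <- dplyr::bind_rows(
    make_labeled("P01", "normal", rep(c("A", "B"), c(9, 1))),
    make_labeled("P02", "normal", rep(c("A", "B"), c(0, 1)))
  )
  tr2 <- dplyr::bind_rows(tr2, make_labeled("P01", "tumor", "C"),
                          make_labeled("P02", "tumor", "C"))
  m2 <- fit_patient_averaged_bayes(tr2, "vj_frame")
  pooled_A <- 9 / 11
  averaged_A <- (9 / 10 + 0 / 1) / 2
  expect_equal(unname(m2$likelihood_normal["A|IGHJ1"]), averaged_A)
  expect_false(isTRUE(all.equal(averaged_A, pooled_A)))

  # single patient: table equals that patient's relative frequencies
  tr3 <- dplyr::bind_rows(make_labeled("P01", "normal", c("A", "A", "B")),
                          make_labeled("P01", "tumor", c("C")))
  m3 <- fit_patient_averaged_bayes(tr3, "vj_frame")
  expect_equal(unname(m3$likelihood_normal["A|IGHJ1"]), 2 / 3)
})

test_that("averaged tables equal the per-patient recount oracle", {
  set.seed(31)
  co <- simulate_cohort(effect_config(n_patients = 5, clones_per_tissue = 40,
                                      seed = 14))
  tr <- suppressMessages(prepare_training_cohort(co, min_reads = 20, seed = 2))
  m <- fit_patient_averaged_bayes(tr, "cdr_length")
  key <- bayes_category(tr, "cdr_length")
  cats <- sort(unique(key))
  for (class in c("normal", "tumor")) {
    sub <- tr$label == class
    tabs <- sapply(unique(tr$patient_id[sub]), function(p) {
      k <- key[sub & tr$patient_id == p]
      as.numeric(table(factor(k, levels = cats))) / length(k)
    })
    oracle <- rowMeans(tabs)
    got <- if (class == "normal") m$likelihood_normal else m$likelihood_tumor
    expect_equal(unname(got[cats]), unname(oracle))
  }
})

test_that("the posterior follows Bayes' theorem with likelihood flooring", {
  tr <- dplyr::bind_rows(
    make_labeled("P01", "normal", c("A", "A", "A", "B")),
    make_labeled("P01", "tumor", c("B", "B", "B", "A"))
  )
  m <- fit_patient_averaged_bayes(tr, "vj_frame")
  # exhaustive check over the table
  for (cat in c("A", "B")) {
    r <- make_records(1, v_call = cat)
    lt <- max(m$likelihood_tumor[paste0(cat, "|IGHJ1")], 1e-9)
    ln <- max(m$likelihood_normal[paste0(cat, "|IGHJ1")], 1e-9)
    expect_equal(predict_bayes(m, r), 0.5 * lt / (0.5 * lt + 0.5 * ln))
  }
  # L_T = 0.3, L_N = 0.1, prior 0.5 -> 0.75
  m$likelihood_tumor["Z|IGHJ1"] <- 0.3
  m$likelihood_normal["Z|IGHJ1"] <- 0.1
  expect_equal(predict_bayes(m, make_records(1, v_call = "Z")), 0.75)
  # unseen category in both tables -> both floored -> 0.5
  expect_equal(predict_bayes(m, make_records(1, v_call = "UNSEEN")), 0.5)
})

test_that("the SHM classifier separates separable data and stays calibrated", {
  shm <- data.frame(shm_fr = rep(c(0, 10), each = 20),
                    shm_cdr = rep(c(0, 10), each = 20))
  labels <- rep(c("tumor", "normal"), each = 20)
  m <- fit_shm_classifier(shm, labels)
  p <- predict_shm(m, shm)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(auc01(p, labels), 1.0)
  expect_true(all(p[1:20] > 0.5) && all(p[21:40] < 0.5))
  expect_error(fit_shm_classifier(shm, rep("tumor", 40)), "class")
})

test_that("hyperparameter draws respect the declared search ranges", {
  space <- default_hyperparameter_space("convnet")
  withr::with_seed(77, {
    for (i in 1:25) {
      h <- bcrclassify:::.sample_convnet_hyper(space)
      expect_gte(h$initial_learning_rate, 1e-7)
      expect_lte(h$initial_learning_rate, 1e-3)
      expect_gte(h$dropout_rate, 0.4)
      expect_lte(h$dropout_rate, 1.0)
      expect_true(h$n_conv_layers %in% 1:2)
      expect_true(h$n_kernels >= 80 && h$n_kernels <= 300)
      expect_true(h$kernel_width %in% 2:3)
      expect_true(h$pool_width %in% 2:3)
      expect_true(h$n_fc_layers %in% 1:3)
      expect_true(h$fc_units >= 100 && h$fc_units <= 300)
    }
  })
  expect_equal(nrow(expand.grid(default_hyperparameter_space("rbf_svm")[c("cost", "gamma")])), 16L)
  expect_equal(default_hyperparameter_space("forest")$max_depth,
               c(floor(sqrt(330)), floor(log2(330)), 330))
  expect_error(fit_sequence_classifier(matrix(0, 4, 4), rep(c("normal", "tumor"), 2),
                                       "forest", budget = 0), "budget")
})

test_that("nested CV holds out whole patients deterministically", {
  set.seed(9)
  co <- simulate_cohort(effect_config(n_patients = 5, clones_per_tissue = 40,
                                      seed = 16))
  tr <- suppressMessages(prepare_training_cohort(co, min_reads = 20, seed = 3))
  res <- nested_cv(tr, spec_bayes("vj_frame"), seed = 6)
  expect_equal(nrow(res$per_patient), length(unique(tr$patient_id)))
  expect_setequal(res$per_patient$patient_id, unique(tr$patient_id))
  # out-of-fold predictions cover every sequence exactly once
  expect_setequal(res$oof$sequence_id, tr$sequence_id)
  res2 <- nested_cv(tr, spec_bayes("vj_frame"), seed = 6)
  expect_identical(res$per_patient, res2$per_patient)
  expect_error(nested_cv(tr[tr$patient_id %in% unique(tr$patient_id)[1:2], ],
                         spec_bayes("vj_frame")), "3 patients")
})
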