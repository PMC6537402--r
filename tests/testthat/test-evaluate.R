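test_that("AUC equals pairwise concordance counting", {
  r <- roc_auc(c(0.9, 0.8, 0.7, 0.1), c("tumor", "normal", "tumor", "normal"))
  expect_equal(r$auc, 0.75)
  expect_equal(roc_auc(c(1, 1, 0, 0), c("tumor", "tumor", "normal", "normal"))$auc, 1)
  set.seed(19)
  scores <- round(runif(200), 2)   # rounding forces ties
  labels <- sample(c("normal", "tumor"), 200, replace = TRUE)
  r2 <- roc_auc(scores, labels)
  expect_equal(r2$auc, brute_force_auc(scores, labels))
  expect_error(roc_auc(1:3, rep("tumor", 3)), "class")
})

test_that("the ROC curve is a monotone staircase from (0,0) to (1,1)", {
  set.seed(23)
  r <- roc_auc(runif(50), sample(c("normal", "tumor"), 50, replace = TRUE,
                                 prob = c(0.6, 0.4)))
  expect_equal(unlist(r$curve[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(r$curve[nrow(r$curve), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))
})

test_that("AUC agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(47)
  scores <- runif(150)
  labels <- sample(c("normal", "tumor"), 150, replace = TRUE)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores, levels = c("normal", "tumor"),
    direction = "<", quiet = TRUE)))
  expect_equal(roc_auc(scores, labels)$auc, ref)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(29)
  scores <- rnorm(100)
  labels <- sample(c("normal", "tumor"), 100, replace = TRUE)
  a <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(plogis(scores), labels)$auc, a)
  expect_equal(roc_auc(exp(scores), labels)$auc, a)
})

test_that("permutation shuffles within patients and uses the add-one estimator", {
  set.seed(37)
  preds <- tibble::tibble(
    patient_id = rep(c("P01", "P02", "P03"), each = 40),
    label = rep(rep(c("normal", "tumor"), each = 20), 3)
  )
  preds$p <- ifelse(preds$label == "tumor", rnorm(120, 2), rnorm(120))
  res <- permutation_test(preds, n_permutations = 999, seed = 3)
  expect_equal(res$p_value, 1 / 1000)  # strong signal beats every permutation
  expect_gt(res$observed, 0.9)

  # constant scores: every permuted statistic ties the observed one
  preds$p <- 0.5
  expect_equal(permutation_test(preds, n_permutations = 99, seed = 1)$p_value, 1)

  # within-patient exchange only: statistic distribution must be centered at
  # 0.5 even when patients have wildly different score scales
  preds$p <- ifelse(preds$patient_id == "P01", rnorm(120, 100), rnorm(120))
  res3 <- permutation_test(preds, n_permutations = 199, seed = 2)
  expect_lt(abs(mean(res3$permuted) - 0.5), 0.05)
})

test_that("paired AUC comparison uses the signed-rank test with Bonferroni", {
  expect_equal(compare_paired_auc(rep(0.7, 10), rep(0.7, 10))$p_value, 1)
  res <- compare_paired_auc(seq(0.6, 0.79, by = 0.01) + 0.1,
                            seq(0.6, 0.79, by = 0.01))
  expect_lt(res$p_value, 0.001)
  # symmetry of the two-sided test
  a <- c(0.6, 0.7, 0.8, 0.55, 0.65, 0.75, 0.62, 0.71)
  b <- c(0.5, 0.75, 0.7, 0.6, 0.6, 0.8, 0.55, 0.68)
  expect_equal(compare_paired_auc(a, b)$p_raw, compare_paired_auc(b, a)$p_raw)
  # Bonferroni clamps at 1
  expect_lte(compare_paired_auc(a, b, n_comparisons = 1000)$p_value, 1)
  expect_error(compare_paired_auc(1:10 / 10, 1:9 / 10), "equal length")
})

test_that("signed-rank p-value agrees with the stats implementation", {
  set.seed(41)
  a <- runif(12, 0.5, 0.9); b <- a + rnorm(12, 0.02, 0.05)
  ours <- compare_paired_auc(a, b)$p_raw
  ref <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE)$p.value)
  expect_equal(ours, ref)
})

test_that("motif matrices cover the trimmed positions with unit columns", {
  set.seed(43)
  n <- 60
  r <- make_records(n, cdr3_aa = replicate(n, paste(
    sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 17, replace = TRUE),
    collapse = "")))
  r$label <- rep(c("normal", "tumor"), each = n / 2)
  p <- ifelse(r$label == "tumor", 0.95, 0.02)
  m <- motif_frequency_matrix(r, p, "CDR3", "correct-tumor")
  expect_equal(nrow(m), 10L)     # 17 - 3 (N side) - 4 (C side)
  expect_equal(ncol(m), 20L)
  expect_true(all(abs(rowSums(m) - 1) < 1e-9))
  m1 <- motif_frequency_matrix(r, p, "CDR1", "correct-normal")
  expect_equal(nrow(m1), 8L)
  # a single confident sequence gives one-hot rows
  r2 <- r[1, ]; r2$label <- "tumor"
  m2 <- motif_frequency_matrix(r2, 0.99, "CDR3", "correct-tumor")
  expect_true(all(apply(m2, 1, max) == 1))
  expect_error(motif_frequency_matrix(r, p, "CDR3", "miscalled-tumor"),
               "census")
})
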