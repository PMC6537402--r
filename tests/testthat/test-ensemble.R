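test_that("ensemble requires all four channels and outputs probabilities", {
  set.seed(8)
  pr <- tibble::tibble(p_vj = runif(100), p_len = runif(100),
                       p_shm = runif(100),
                       p_seq = plogis(rnorm(100, rep(c(-1.5, 1.5), each = 50))),
                       label = rep(c("normal", "tumor"), each = 50))
  expect_error(fit_ensemble(pr[, -2]), "p_len")
  m <- fit_ensemble(pr)
  p <- predict_ensemble(m, pr)
  expect_true(all(p >= 0 & p <= 1))
  expect_length(m$coefficients, 5L)
})

test_that("the informative channel receives the dominant coefficient", {
  set.seed(10)
  for (rep in 1:5) {
    n <- 300
    y <- rep(c("normal", "tumor"), each = n / 2)
    pr <- tibble::tibble(
      p_vj = runif(n), p_len = runif(n), p_shm = runif(n),
      p_seq = plogis(rnorm(n, ifelse(y == "tumor", 1.5, -1.5))),
      label = y
    )
    m <- fit_ensemble(pr)
    w <- abs(m$coefficients[c("p_vj", "p_len", "p_shm", "p_seq")])
    expect_equal(names(which.max(w)), "p_seq")
  }
})

test_that("constant channels give constant chance-level predictions", {
  pr <- tibble::tibble(p_vj = 0.5, p_len = 0.5, p_shm = 0.5, p_seq = 0.5,
                       label = rep(c("normal", "tumor"), each = 25))[rep(1, 50), ]
  pr$label <- rep(c("normal", "tumor"), each = 25)
  m <- fit_ensemble(pr)
  p <- predict_ensemble(m, pr)
  expect_lt(diff(range(p)), 1e-12)
})

test_that("ensemble predictions match the logistic linear form", {
  set.seed(11)
  pr <- tibble::tibble(p_vj = runif(200), p_len = runif(200), p_shm = runif(200),
                       p_seq = runif(200),
                       label = rep(c("normal", "tumor"), 100))
  pr$label[pr$p_seq > 0.5] <- "tumor"  # give the booster signal
  m <- fit_ensemble(pr)
  co <- m$coefficients
  x <- as.matrix(pr[, c("p_vj", "p_len", "p_shm", "p_seq")])
  manual <- plogis(co["intercept"] + x %*% co[-1])
  expect_equal(unname(predict_ensemble(m, pr)), as.numeric(manual),
               tolerance = 1e-5)
})

test_that("tissue scores implement mean, median and histogram mode", {
  expect_equal(tissue_score(c(0.2, 0.4, 0.9), "mean"), 0.5)
  expect_equal(tissue_score(c(0.2, 0.4, 0.9), "median"), 0.4)
  # three values cluster in [0.70, 0.72] bins; mode midpoint of fullest bin
  p <- c(0.70, 0.71, 0.712, 0.10)
  m <- tissue_score(p, "mode", bin_width = 0.02)
  expect_equal(m, 0.71)
  expect_error(tissue_score(numeric(0), "mean"), "empty")
  # mean statistic is order-invariant and linear
  set.seed(2); q <- runif(20)
  expect_equal(tissue_score(q, "mean"), tissue_score(rev(q), "mean"))
})

test_that("an uninformative entropy channel leaves tissue AUC unchanged", {
  set.seed(12)
  samples <- tibble::tibble(
    patient_id = rep(sprintf("P%02d", 1:20), each = 2),
    tissue = rep(c("normal", "tumor"), 20),
    score = plogis(rnorm(40, ifelse(rep(c(0, 1), 20) == 1, 1, -1))),
    entropy = 5
  )
  res <- augment_with_entropy(samples)
  expect_equal(res$auc_with, res$auc_without, tolerance = 1e-6)
  expect_equal(nrow(res$augmented), 40L)
})
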