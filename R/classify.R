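#' Feature category of each record for the Bayes classifiers
#'
#' `vj_frame`: the (V, J) gene pair (allele-normalized);
#' `cdr_length`: the (L1, L2, L3) CDR amino-acid length triple.
#'
#' @param records repertoire tibble.
#' @param feature_kind `"vj_frame"` or `"cdr_length"`.
#' @return character vector of category keys.
#' @export
bayes_category <- function(records, feature_kind = c("vj_frame", "cdr_length")) {
  feature_kind <- match.arg(feature_kind)
  if (feature_kind == "vj_frame") {
    paste(normalize_gene_call(records$v_call),
          normalize_gene_call(records$j_call), sep = "|")
  } else {
    paste(nchar(records$cdr1_aa), nchar(records$cdr2_aa),
          nchar(records$cdr3_aa), sep = "|")
  }
}

#' Fit a patient-averaged Bayes classifier
#'
#' For each class (normal/tumor), computes every training patient's
#' relative-frequency table over the feature categories and averages the
#' tables with equal patient weight — *not* pooled counts, so large
#' patients do not dominate the likelihood. A patient contributing no
#' sequences of a class is skipped for that class's table.
#'
#' @param records labeled training records: columns of the repertoire
#'   format plus `label` (`"normal"`/`"tumor"`).
#' @param feature_kind `"vj_frame"` or `"cdr_length"`.
#' @param prior_tumor class prior used at prediction (default 0.5; the
#'   clone-sampling design makes training data near-balanced).
#' @param smoothing_epsilon likelihood floor applied at prediction time.
#' @return a `pa_bayes` model with `likelihood_normal` and
#'   `likelihood_tumor` named vectors (each sums to 1).
#' @export
fit_patient_averaged_bayes <- function(records,
                                       feature_kind = c("vj_frame", "cdr_length"),
                                       prior_tumor = 0.5,
                                       smoothing_epsilon = 1e-9) {
  feature_kind <- match.arg(feature_kind)
  .assert(nrow(records) > 0, "empty training set")
  .assert("label" %in% names(records), "records must carry a label column")
  cat_key <- bayes_category(records, feature_kind)
  cats <- sort(unique(cat_key))
  class_table <- function(class) {
    sub <- records$label == class
    .assert(any(sub), paste0("no training sequences of class ", class))
    pats <- unique(records$patient_id[sub])
    tabs <- vapply(pats, function(p) {
      keys <- cat_key[sub & records$patient_id == p]
      tab <- table(factor(keys, levels = cats))
      as.numeric(tab) / length(keys)
    }, numeric(length(cats)))
    tab <- rowMeans(matrix(tabs, nrow = length(cats)))
    stats::setNames(tab, cats)
  }
  structure(list(
    feature_kind = feature_kind,
    likelihood_normal = class_table("normal"),
    likelihood_tumor = class_table("tumor"),
    n_patients_train = length(unique(records$patient_id)),
    prior_tumor = prior_tumor,
    smoothing_epsilon = smoothing_epsilon
  ), class = "pa_bayes")
}

#' Posterior tumor probability from a patient-averaged Bayes model
#'
#' Bayes' theorem on the averaged likelihood tables:
#' `P(T|c) = prior * L_T(c) / (prior * L_T(c) + (1-prior) * L_N(c))`,
#' with both likelihoods floored at the smoothing epsilon so unseen
#' categories give 0.5 under the default prior.
#'
#' @param model a `pa_bayes` model.
#' @param records repertoire records to score.
#' @return numeric vector of tumor probabilities.
#' @export
predict_bayes <- function(model, records) {
  keys <- bayes_category(records, model$feature_kind)
  eps <- model$smoothing_epsilon
  lt <- pmax(model$likelihood_tumor[keys], eps, na.rm = TRUE)
  ln <- pmax(model$likelihood_normal[keys], eps, na.rm = TRUE)
  lt[is.na(lt)] <- eps
  ln[is.na(ln)] <- eps
  pt <- model$prior_tumor
  unname(pt * lt / (pt * lt + (1 - pt) * ln))
}

#' Fit the linear-kernel SHM classifier
#'
#' A linear support-vector classifier on the two-dimensional feature
#' (SHM count in framework regions, SHM count in CDRs), with a logistic
#' calibration of the decision value fitted on the training data so the
#' output is a probability.
#'
#' @param shm data frame or tibble with columns `shm_fr`, `shm_cdr`.
#' @param labels `"normal"`/`"tumor"` labels, both classes present.
#' @return an `shm_model`.
#' @export
fit_shm_classifier <- function(shm, labels) {
  y <- .label01(labels)
  .assert(length(unique(y)) == 2, "training set must contain both classes")
  x <- as.matrix(shm[, c("shm_fr", "shm_cdr")])
  fit <- e1071::svm(x, factor(y), kernel = "linear", scale = FALSE)
  dv <- attr(stats::predict(fit, x, decision.values = TRUE), "decision.values")
  dec <- as.numeric(dv)
  # orient the decision value so larger means tumor ("0/1" = positive is normal)
  sgn <- if (colnames(dv)[1] == "0/1") -1 else 1
  calib <- suppressWarnings(
    stats::glm(y ~ d, family = stats::binomial(), data = data.frame(y = y, d = sgn * dec))
  )
  structure(list(svm = fit, calib = calib, sgn = sgn), class = "shm_model")
}

#' Predict tumor probability from SHM counts
#' @param model an `shm_model`.
#' @param shm data frame with `shm_fr`, `shm_cdr`.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict_shm <- function(model, shm) {
  x <- as.matrix(shm[, c("shm_fr", "shm_cdr")])
  dec <- as.numeric(attr(stats::predict(model$svm, x, decision.values = TRUE),
                         "decision.values"))
  p <- stats::predict(model$calib, newdata = data.frame(d = model$sgn * dec),
                      type = "response")
  unname(pmin(pmax(p, 0), 1))
}

#' Default hyperparameter search spaces
#'
#' The convolutional classifier searches (log-uniform learning rate in
#' `[1e-7, 1e-3]`; dropout keep-probability in `[0.4, 1.0]`; 1-2 conv
#' layers of 80-300 kernels of width 2-3 with pooling width 2-3; 1-3 fully
#' connected layers of 100-300 units). The RBF-kernel classifier searches
#' the grid `C` in `{1, 10, 100, 1000}` x `gamma` in
#' `{1e-2, 1e-3, 1e-4, 1e-5}`. The forest searches maximum tree depth in
#' `{sqrt(f), log2(f), f}` with `f = 330` features.
#'
#' @param algorithm `"convnet"`, `"rbf_svm"` or `"forest"`.
#' @param n_features feature count `f` for the forest depth grid.
#' @return a `hyper_space` list describing the ranges.
#' @export
default_hyperparameter_space <- function(algorithm = c("convnet", "rbf_svm", "forest"),
                                         n_features = 330) {
  algorithm <- match.arg(algorithm)
  space <- switch(algorithm,
    convnet = list(
      initial_learning_rate = c(1e-7, 1e-3),
      dropout_rate = c(0.4, 1.0),
      n_conv_layers = c(1L, 2L),
      n_kernels = c(80L, 300L),
      kernel_width = c(2L, 3L),
      pool_width = c(2L, 3L),
      n_fc_layers = c(1L, 2L, 3L),
      fc_units = c(100L, 300L)
    ),
    rbf_svm = list(cost = 10^(0:3), gamma = 10^(-(2:5))),
    forest = list(max_depth = c(floor(sqrt(n_features)),
                                floor(log2(n_features)), n_features))
  )
  structure(c(space, list(algorithm = algorithm)), class = "hyper_space")
}

# draw one random convnet configuration from the space
.sample_convnet_hyper <- function(space) {
  lr_rng <- log10(space$initial_learning_rate)
  list(
    initial_learning_rate = 10^stats::runif(1, lr_rng[1], lr_rng[2]),
    dropout_rate = stats::runif(1, space$dropout_rate[1], space$dropout_rate[2]),
    n_conv_layers = sample(space$n_conv_layers, 1),
    n_kernels = sample(space$n_kernels[1]:space$n_kernels[2], 1),
    kernel_width = sample(space$kernel_width, 1),
    pool_width = sample(space$pool_width, 1),
    n_fc_layers = sample(space$n_fc_layers, 1),
    fc_units = sample(space$fc_units[1]:space$fc_units[2], 1)
  )
}

.candidate_hypers <- function(space, search, budget) {
  if (space$algorithm == "convnet") {
    .assert(search == "random", "the convnet space is searched randomly")
    lapply(seq_len(budget), function(i) .sample_convnet_hyper(space))
  } else if (space$algorithm == "rbf_svm") {
    grid <- expand.grid(cost = space$cost, gamma = space$gamma)
    lapply(seq_len(nrow(grid)), function(i) as.list(grid[i, ]))
  } else {
    lapply(space$max_depth, function(d) list(max_depth = d))
  }
}

.fit_one_seq_model <- function(x, y01, algorithm, hyper, seed, epochs) {
  if (algorithm == "convnet") {
    fit_convnet(x, y01, hyper, epochs = epochs, seed = seed)
  } else if (algorithm == "rbf_svm") {
    fit <- e1071::svm(x, factor(y01), kernel = "radial",
                      cost = hyper$cost, gamma = hyper$gamma, scale = FALSE)
    dv <- attr(stats::predict(fit, x, decision.values = TRUE), "decision.values")
    dec <- as.numeric(dv)
    sgn <- if (colnames(dv)[1] == "0/1") -1 else 1
    calib <- suppressWarnings(
      stats::glm(y ~ d, family = stats::binomial(),
                 data = data.frame(y = y01, d = sgn * dec))
    )
    structure(list(svm = fit, calib = calib, sgn = sgn), class = "rbf_model")
  } else {
    withr::local_seed(.subseed(seed, 5))
    df <- as.data.frame(x)
    df$.y <- factor(y01)
    structure(list(rf = ranger::ranger(
      dependent.variable.name = ".y", data = df, probability = TRUE,
      max.depth = hyper$max_depth, num.trees = 200,
      seed = .subseed(seed, 6), num.threads = 1
    )), class = "forest_model")
  }
}

.predict_one_seq_model <- function(model, x) {
  if (inherits(model, "convnet")) {
    predict_convnet(model, x)
  } else if (inherits(model, "rbf_model")) {
    dec <- as.numeric(attr(stats::predict(model$svm, x, decision.values = TRUE),
                           "decision.values"))
    p <- stats::predict(model$calib, newdata = data.frame(d = model$sgn * dec),
                        type = "response")
    unname(pmin(pmax(p, 0), 1))
  } else {
    pr <- stats::predict(model$rf, data = as.data.frame(x),
                         num.threads = 1)$predictions
    unname(pr[, "1"])
  }
}

#' Fit a per-sequence classifier on encoded CDR features
#'
#' Trains one of three models on the flattened 330-dimensional Kidera
#' feature rows: the 1-D convolutional network ([fit_convnet()]), an
#' RBF-kernel support-vector classifier, or a random forest.
#' Hyperparameters are chosen inside `space` by the stated search strategy
#' (`budget` random draws, or the full grid) using an internal two-fold
#' cross-validation — split at the group (patient) level when `groups` is
#' given — then the selected configuration is refit on all rows.
#'
#' @param x numeric feature matrix (rows = sequences).
#' @param labels `"normal"`/`"tumor"` labels.
#' @param algorithm `"convnet"`, `"rbf_svm"` or `"forest"`.
#' @param space a `hyper_space`; defaults to
#'   [default_hyperparameter_space()] for the algorithm.
#' @param search `"random"` or `"grid"`; defaults to random for the
#'   convnet and the full grid otherwise.
#' @param budget number of random draws (convnet; default 10).
#' @param seed integer seed.
#' @param groups optional grouping vector (e.g. patient ids) for the
#'   internal two-fold split.
#' @param epochs convnet training epochs.
#' @return a `seq_classifier` with the selected hyperparameters.
#' @export
fit_sequence_classifier <- function(x, labels,
                                    algorithm = c("convnet", "rbf_svm", "forest"),
                                    space = NULL, search = NULL, budget = 10,
                                    seed = 1, groups = NULL, epochs = 30) {
  algorithm <- match.arg(algorithm)
  .assert(budget >= 1, "budget must be >= 1")
  y01 <- .label01(labels)
  .assert(length(unique(y01)) == 2, "training set must contain both classes")
  space <- space %||% default_hyperparameter_space(algorithm, ncol(x))
  search <- search %||% if (algorithm == "convnet") "random" else "grid"
  withr::local_seed(.subseed(seed, 7))
  cands <- .candidate_hypers(space, search, budget)
  best <- cands[[1]]
  if (length(cands) > 1) {
    fold <- .two_fold_split(groups %||% seq_along(y01), seed)
    score <- vapply(seq_along(cands), function(ci) {
      aucs <- vapply(1:2, function(f) {
        tr <- fold != f
        if (length(unique(y01[tr])) < 2 || length(unique(y01[!tr])) < 2) {
          return(NA_real_)
        }
        m <- .fit_one_seq_model(x[tr, , drop = FALSE], y01[tr], algorithm,
                                cands[[ci]], .subseed(seed, 100 + ci), epochs)
        .auc01(.predict_one_seq_model(m, x[!tr, , drop = FALSE]), y01[!tr])
      }, numeric(1))
      mean(aucs, na.rm = TRUE)
    }, numeric(1))
    best <- cands[[which.max(score)]]
  }
  model <- .fit_one_seq_model(x, y01, algorithm, best, .subseed(seed, 8), epochs)
  structure(list(model = model, algorithm = algorithm, hyper = best),
            class = "seq_classifier")
}

#' Predict tumor probabilities from a fitted sequence classifier
#' @param model a `seq_classifier`.
#' @param x feature matrix as used in training.
#' @return numeric vector of tumor probabilities.
#' @export
predict_sequence_classifier <- function(model, x) {
  .predict_one_seq_model(model$model, x)
}

# assign groups to two folds, balanced by group count
.two_fold_split <- function(groups, seed) {
  withr::local_seed(.subseed(seed, 9))
  g <- unique(groups)
  half <- sample(g, ceiling(length(g) / 2))
  ifelse(groups %in% half, 1L, 2L)
}

#' Model specifications for the cross-validation harness
#'
#' Bundles a fit function and a predict function over labeled repertoire
#' records for use with [nested_cv()].
#'
#' @param feature_kind Bayes feature (`"vj_frame"` or `"cdr_length"`).
#' @return a `model_spec` list with elements `name`, `fit(records, seed)`
#'   and `predict(model, records)`.
#' @name model-specs
NULL

#' @rdname model-specs
#' @export
spec_bayes <- function(feature_kind = c("vj_frame", "cdr_length")) {
  feature_kind <- match.arg(feature_kind)
  list(
    name = if (feature_kind == "vj_frame") "vj" else "len",
    fit = function(records, seed) fit_patient_averaged_bayes(records, feature_kind),
    predict = function(model, records) predict_bayes(model, records)
  )
}

#' @rdname model-specs
#' @export
spec_shm <- function() {
  list(
    name = "shm",
    fit = function(records, seed) fit_shm_classifier(records, records$label),
    predict = function(model, records) predict_shm(model, records)
  )
}

#' @param algorithm,budget,epochs passed to [fit_sequence_classifier()].
#' @param targets CDR target lengths for the encoding.
#' @param mode trimming/padding mode.
#' @rdname model-specs
#' @export
spec_seq <- function(algorithm = "convnet", budget = 10, epochs = 30,
                     targets = c(8, 8, 17), mode = "center") {
  list(
    name = paste0("seq_", algorithm),
    fit = function(records, seed) {
      x <- encode_repertoire(records, targets, mode)
      fit_sequence_classifier(x, records$label, algorithm, budget = budget,
                              seed = seed, groups = records$patient_id,
                              epochs = epochs)
    },
    predict = function(model, records) {
      predict_sequence_classifier(model, encode_repertoire(records, targets, mode))
    }
  )
}

#' Patient-level nested cross-validation
#'
#' Outer loop: leave-one-patient-out; the model (including any internal
#' hyperparameter selection, which uses a two-fold patient-level split of
#' the outer training patients) is fit on all other patients and scored on
#' every held-out sequence. Sequences are always split at the patient
#' level, never at the sequence level.
#'
#' @param records labeled records (`label` column) of at least 3 patients.
#' @param spec a model specification ([spec_bayes()], [spec_shm()],
#'   [spec_seq()]).
#' @param seed integer seed.
#' @return list with `per_patient` (tibble `patient_id`, `auc`, `n`; AUC is
#'   `NA` for a held-out patient with fewer than 2 sequences of either
#'   class, and such patients are logged via a message) and `oof` (tibble
#'   of out-of-fold probabilities: `sequence_id`, `patient_id`, `label`,
#'   `p`).
#' @export
nested_cv <- function(records, spec, seed = 1) {
  pats <- unique(records$patient_id)
  .assert(length(pats) >= 3, "nested CV needs at least 3 patients")
  per_pat <- vector("list", length(pats))
  oof <- vector("list", length(pats))
  for (i in seq_along(pats)) {
    p <- pats[i]
    tr <- records[records$patient_id != p, , drop = FALSE]
    te <- records[records$patient_id == p, , drop = FALSE]
    .assert(!any(te$patient_id %in% tr$patient_id),
            "internal error: patient on both sides of a split")
    model <- spec$fit(tr, .subseed(seed, 20 + i))
    prob <- spec$predict(model, te)
    y <- .label01(te$label)
    auc <- if (min(sum(y == 1), sum(y == 0)) >= 2) .auc01(prob, y) else NA_real_
    if (is.na(auc)) {
      message("patient ", p, " skipped for AUC: fewer than 2 sequences of a class")
    }
    per_pat[[i]] <- tibble(patient_id = p, auc = auc, n = nrow(te))
    oof[[i]] <- tibble(sequence_id = te$sequence_id, patient_id = p,
                       label = te$label, p = prob)
  }
  list(per_patient = dplyr::bind_rows(per_pat), oof = dplyr::bind_rows(oof))
}
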