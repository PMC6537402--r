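test_that("the three-mismatch boundary splits families as defined", {
  nt <- strrep("ACG", 17)
  r <- make_records(2, cdr3 = c(nt, mutate_nt_at(nt, c(1, 5, 9))))
  fams <- assign_clonal_families(r)
  expect_equal(nrow(fams), 1L)
  r4 <- make_records(2, cdr3 = c(nt, mutate_nt_at(nt, c(1, 5, 9, 13))))
  expect_equal(nrow(assign_clonal_families(r4)), 2L)
})

test_that("a single record forms a singleton family", {
  fams <- assign_clonal_families(make_records(1))
  expect_equal(nrow(fams), 1L)
  expect_equal(fams$n_members, 1L)
})

test_that("clonotyping refuses multi-patient input", {
  r <- make_records(4, patient_id = c("P01", "P01", "P02", "P02"))
  expect_error(assign_clonal_families(r), "patient")
})

test_that("assignment matches the brute-force transitive-closure oracle", {
  set.seed(101)
  for (rep in 1:5) {
    n <- 25
    base_nts <- replicate(4, paste(sample(c("A", "C", "G", "T"), 30,
                                          replace = TRUE), collapse = ""))
    cdr3 <- vapply(seq_len(n), function(i) {
      mutate_nt(sample(base_nts, 1), sample(0:4, 1))
    }, character(1))
    r <- make_records(n,
      v_call = sample(c("IGHV1*01", "IGHV1*02", "IGHV2"), n, replace = TRUE),
      j_call = sample(c("IGHJ4", "IGHJ6"), n, replace = TRUE),
      cdr3_aa = strrep("A", 10), cdr3 = cdr3)
    fams <- assign_clonal_families(r)
    got <- dplyr::bind_rows(fams$members)
    got <- got[match(r$sequence_id, got$sequence_id), ]
    oracle <- brute_force_clonotype(r)
    # same partition: clone ids and oracle components induce the same blocks
    expect_equal(length(unique(got$clone_id)), length(unique(oracle)))
    expect_true(all(tapply(oracle, got$clone_id,
                           function(x) length(unique(x))) == 1))
    # partition property: every record in exactly one family
    expect_setequal(got$sequence_id, r$sequence_id)
    expect_equal(sum(fams$n_members), n)
  }
})

test_that("dominant-clone extraction applies the read and purity thresholds", {
  fam <- function(reads_tumor, reads_normal) {
    n_t <- length(reads_tumor); n_n <- length(reads_normal)
    r <- make_records(n_t + n_n,
                      tissue = c(rep("tumor", n_t), rep("normal", n_n)),
                      duplicate_count = c(reads_tumor, reads_normal),
                      cdr3 = strrep("ACG", 17))
    assign_clonal_families(r)
  }
  expect_equal(nrow(extract_dominant_clones(fam(49, integer(0)))), 0L)
  kept <- extract_dominant_clones(fam(50, integer(0)))
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$specific_label, "tumor")
  # 45 tumor + 5 normal reads: purity exactly 0.90, included as tumor
  kept <- extract_dominant_clones(fam(45, 5))
  expect_equal(kept$specific_label, "tumor")
  # 25 + 25: purity 0.5, excluded
  expect_equal(nrow(extract_dominant_clones(fam(25, 25))), 0L)
})

test_that("raising thresholds never adds extracted clones", {
  set.seed(5)
  co <- simulate_cohort(effect_config(n_patients = 1, clones_per_tissue = 60,
                                      contamination_rate = 0.3, seed = 9))
  fams <- assign_clonal_families(co)
  n_prev <- Inf
  for (mr in c(10, 50, 200)) {
    n_now <- nrow(extract_dominant_clones(fams, min_reads = mr))
    expect_lte(n_now, n_prev)
    n_prev <- n_now
  }
  n_prev <- Inf
  for (pu in c(0.6, 0.9, 0.99)) {
    n_now <- nrow(extract_dominant_clones(fams, purity_threshold = pu))
    expect_lte(n_now, n_prev)
    n_prev <- n_now
  }
})

test_that("training-sequence sampling is capped, duplicate-free and seeded", {
  r <- make_records(12, tissue = "tumor", duplicate_count = 10L,
                    cdr3 = strrep("ACG", 17))
  fams <- extract_dominant_clones(assign_clonal_families(r))
  s1 <- sample_training_sequences(fams, k = 3, seed = 4)
  expect_equal(nrow(s1), 3L)
  expect_equal(anyDuplicated(s1$sequence_id), 0L)
  expect_true(all(s1$label == "tumor"))
  expect_identical(s1, sample_training_sequences(fams, k = 3, seed = 4))
  # family smaller than k returns all members
  r2 <- make_records(2, tissue = "tumor", duplicate_count = 30L,
                     cdr3 = strrep("ACG", 17))
  fams2 <- extract_dominant_clones(assign_clonal_families(r2))
  expect_equal(nrow(sample_training_sequences(fams2, k = 3, seed = 1)), 2L)
})

test_that("CDR3 sharing fractions count cross-patient overlap per tissue", {
  r <- dplyr::bind_rows(
    make_records(2, patient_id = "P01", cdr3_aa = c(strrep("A", 10), strrep("C", 10))),
    make_records(2, patient_id = "P02", cdr3_aa = c(strrep("A", 10), strrep("D", 10)))
  )
  sh <- cdr3_sharing_fraction(r)
  expect_equal(sh$sharing, c(0.5, 0.5))
  r_disjoint <- dplyr::bind_rows(
    make_records(2, patient_id = "P01", cdr3_aa = c(strrep("A", 10), strrep("C", 10))),
    make_records(2, patient_id = "P02", cdr3_aa = c(strrep("E", 10), strrep("D", 10)))
  )
  expect_true(all(cdr3_sharing_fraction(r_disjoint)$sharing == 0))
  r_same <- dplyr::bind_rows(
    make_records(2, patient_id = "P01", cdr3_aa = c(strrep("A", 10), strrep("C", 10))),
    make_records(2, patient_id = "P02", cdr3_aa = c(strrep("A", 10), strrep("C", 10)))
  )
  expect_true(all(cdr3_sharing_fraction(r_same)$sharing == 1))
  expect_error(cdr3_sharing_fraction(make_records(3)), "two patients")
})

test_that("clonal entropy matches the direct Shannon formula", {
  expect_equal(clonal_entropy(rep(10, 4)), 2)
  expect_equal(clonal_entropy(7), 0)
  set.seed(3)
  reads <- sample(1:500, 10)
  p <- reads / sum(reads)
  expect_equal(clonal_entropy(reads), -sum(p * log2(p)))
})
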