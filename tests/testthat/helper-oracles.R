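# independent oracles and fixture builders used across the suite

# construct valid records from minimal arguments
make_records <- function(n, patient_id = "P01", tissue = "normal",
                         v_call = "IGHV01", j_call = "IGHJ1",
                         cdr3_aa = NULL, cdr3 = NULL,
                         duplicate_count = 1L, shm_fr = 0L, shm_cdr = 0L,
                         cdr1_aa = "ACDEFGHI", cdr2_aa = "KLMNPQRS") {
  if (is.null(cdr3_aa)) cdr3_aa <- rep(strrep("A", 17), n)
  if (is.null(cdr3)) {
    cdr3 <- vapply(nchar(cdr3_aa) * 3L, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1))
  }
  tibble::tibble(
    sequence_id = sprintf("seq%04d", seq_len(n)),
    patient_id = rep_len(patient_id, n), tissue = rep_len(tissue, n),
    v_call = rep_len(v_call, n), j_call = rep_len(j_call, n),
    cdr1_aa = rep_len(cdr1_aa, n), cdr2_aa = rep_len(cdr2_aa, n),
    cdr3_aa = rep_len(cdr3_aa, n), cdr3 = rep_len(cdr3, n),
    duplicate_count = as.integer(rep_len(duplicate_count, n)),
    shm_fr = as.integer(rep_len(shm_fr, n)),
    shm_cdr = as.integer(rep_len(shm_cdr, n))
  )
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# O(n^2) transitive closure of the pairwise clonotype criterion graph
brute_force_clonotype <- function(records, max_mismatch = 3) {
  n <- nrow(records)
  adj <- matrix(FALSE, n, n)
  v <- bcrclassify::normalize_gene_call(records$v_call)
  j <- bcrclassify::normalize_gene_call(records$j_call)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      adj[a, b] <- v[a] == v[b] && j[a] == j[b] &&
        nchar(records$cdr3[a]) == nchar(records$cdr3[b]) &&
        hamming(records$cdr3[a], records$cdr3[b]) <= max_mismatch
    }
  }
  # Warshall closure
  for (k in seq_len(n)) {
    adj <- adj | (adj[, k] %o% adj[k, ])
  }
  comp <- integer(n)
  cid <- 0L
  for (a in seq_len(n)) {
    if (comp[a] == 0L) {
      cid <- cid + 1L
      comp[adj[a, ]] <- cid
    }
  }
  comp
}

# O(n^2) pairwise-enumeration AUC oracle
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == "tumor"]
  neg <- scores[labels == "normal"]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

mutate_nt_at <- function(s, pos) {
  chars <- strsplit(s, "")[[1]]
  for (p in pos) chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
  paste(chars, collapse = "")
}

# random mutated copies of a CDR3 nucleotide string
mutate_nt <- function(s, k) {
  chars <- strsplit(s, "")[[1]]
  pos <- sample(length(chars), k)
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  paste(chars, collapse = "")
}

auc01 <- function(scores, labels) {
  y <- as.integer(labels == "tumor")
  r <- rank(scores)
  n1 <- sum(y); n0 <- sum(1 - y)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
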