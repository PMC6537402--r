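#' Normalize a V/J gene call to the gene level
#'
#' Strips allele suffixes (`*01` etc.) so that distinct alleles of one gene
#' compare equal in the clonotype criteria.
#'
#' @param call character vector of gene-segment calls.
#' @return character vector of gene-level names.
#' @export
normalize_gene_call <- function(call) {
  sub("\\*.*$", "", call)
}

# single-linkage components under Hamming distance <= max_mismatch among
# equal-length nucleotide strings; returns integer component ids
.hamming_components <- function(seqs, max_mismatch = 3L) {
  n <- length(seqs)
  if (n == 1L) return(1L)
  mat <- do.call(rbind, strsplit(seqs, ""))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n - 1L)) {
    mi <- mat[i, ]
    for (j in seq.int(i + 1L, n)) {
      if (sum(mi != mat[j, ]) <= max_mismatch) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Group a patient's sequences into clonal families
#'
#' Two sequences belong to the same clonal family iff they are connected
#' under the pairwise relation "same V and J gene (allele-normalized), same
#' CDR3 nucleotide length, and at most `max_mismatch` nucleotide mismatches
#' in CDR3" — i.e. single-linkage transitive closure within each
#' (V, J, length) block.
#'
#' @param records repertoire records of a single patient, both tissues
#'   pooled; non-empty `cdr3`.
#' @param max_mismatch maximum CDR3 Hamming distance joining two sequences
#'   (default 3).
#' @param normalize_alleles normalize V/J calls to the gene level before
#'   comparison (default TRUE).
#' @return a clonal-family tibble: one row per family with `clone_id`,
#'   `v_call`, `j_call`, `cdr3_length_nt`, `n_members`, `reads_total`,
#'   `reads_tumor`, `purity` (max of the tumor and normal read fraction),
#'   `specific_label` (`NA` until [extract_dominant_clones()]) and a
#'   `members` list-column holding the member records (with `clone_id`
#'   filled in).
#' @export
assign_clonal_families <- function(records, max_mismatch = 3L,
                                   normalize_alleles = TRUE) {
  .assert(nrow(records) > 0, "no records")
  .assert(length(unique(records$patient_id)) == 1L,
          "clonotyping is per-patient: records span multiple patients")
  .assert(all(nchar(records$cdr3) > 0), "empty cdr3 nucleotide sequence")
  v <- if (normalize_alleles) normalize_gene_call(records$v_call) else records$v_call
  j <- if (normalize_alleles) normalize_gene_call(records$j_call) else records$j_call
  block <- paste(v, j, nchar(records$cdr3), sep = "|")
  clone_of <- character(nrow(records))
  for (b in unique(block)) {
    idx <- which(block == b)
    comp <- .hamming_components(records$cdr3[idx], max_mismatch)
    clone_of[idx] <- paste0(b, "|", comp)
  }
  # stable ids in order of first appearance
  ids <- unique(clone_of)
  clone_id <- sprintf("%s_clone%04d", records$patient_id[1],
                      match(clone_of, ids))
  records$clone_id <- clone_id
  fams <- records %>%
    dplyr::group_by(clone_id) %>%
    dplyr::summarise(
      v_call = normalize_gene_call(.data$v_call[1]),
      j_call = normalize_gene_call(.data$j_call[1]),
      cdr3_length_nt = nchar(.data$cdr3[1]),
      n_members = dplyr::n(),
      reads_total = sum(.data$duplicate_count),
      reads_tumor = sum(.data$duplicate_count[.data$tissue == "tumor"]),
      members = list(dplyr::pick(dplyr::everything())),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      purity = pmax(.data$reads_tumor, .data$reads_total - .data$reads_tumor) /
        .data$reads_total,
      specific_label = NA_character_
    )
  # pick() drops the grouping column; restore clone_id inside each member set
  fams$members <- purrr::map2(fams$members, fams$clone_id, function(m, id) {
    m$clone_id <- id
    m
  })
  fams
}

#' Extract dominant tissue-specific clones
#'
#' Keeps clonal families with at least `min_reads` supporting reads (to
#' suppress sequencing-error clones) whose read content is at least
#' `purity_threshold` from a single tissue; each kept family is labeled with
#' that majority tissue.
#'
#' @param families output of [assign_clonal_families()].
#' @param min_reads minimum total read count (default 50).
#' @param purity_threshold minimum majority-tissue read fraction
#'   (default 0.9).
#' @return the filtered families with `specific_label` set to `"normal"` or
#'   `"tumor"`.
#' @export
extract_dominant_clones <- function(families, min_reads = 50,
                                    purity_threshold = 0.9) {
  families %>%
    dplyr::filter(.data$reads_total >= min_reads,
                  .data$purity >= purity_threshold) %>%
    dplyr::mutate(
      specific_label = ifelse(.data$reads_tumor >= .data$reads_total / 2,
                              "tumor", "normal")
    )
}

#' Sample training sequences from labeled clones
#'
#' Draws `min(k, n_members)` distinct member sequences uniformly without
#' replacement from every family, to remove clone-size bias from the
#' training set. Each returned record carries its family's tissue label in
#' a `label` column.
#'
#' @param families labeled families (from [extract_dominant_clones()]).
#' @param k sequences per clone (default 3).
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return a repertoire tibble with `clone_id` and `label` columns.
#' @export
sample_training_sequences <- function(families, k = 3, seed = 1) {
  .assert(all(families$specific_label %in% c("normal", "tumor")),
          "families must carry a specific_label; run extract_dominant_clones()")
  withr::local_seed(.subseed(seed, 11))
  out <- purrr::map2(families$members, families$specific_label, function(m, lab) {
    take <- min(k, nrow(m))
    idx <- sample.int(nrow(m), take)
    m <- m[idx, , drop = FALSE]
    m$label <- lab
    m
  })
  dplyr::bind_rows(out)
}

#' Fraction of CDR3 amino-acid sequences shared between patients
#'
#' For each patient and tissue, the fraction of that patient's unique CDR3
#' amino-acid sequences that are observed in at least one other patient's
#' repertoire of the same tissue.
#'
#' @param cohort repertoire records from at least two patients.
#' @return tibble with `patient_id`, `tissue`, `n_unique`, `sharing`.
#' @export
cdr3_sharing_fraction <- function(cohort) {
  .assert(length(unique(cohort$patient_id)) >= 2,
          "sharing requires at least two patients")
  cohort %>%
    dplyr::distinct(.data$patient_id, .data$tissue, .data$cdr3_aa) %>%
    dplyr::group_by(.data$tissue, .data$cdr3_aa) %>%
    dplyr::mutate(.n_pat = dplyr::n_distinct(.data$patient_id)) %>%
    dplyr::group_by(.data$patient_id, .data$tissue) %>%
    dplyr::summarise(
      n_unique = dplyr::n(),
      sharing = mean(.data$.n_pat > 1),
      .groups = "drop"
    )
}

#' Clonal entropy of a repertoire
#'
#' Shannon entropy (base 2) of the clone-abundance distribution
#' `p_i = reads_i / sum(reads)`.
#'
#' @param x either a clonal-family tibble (uses `reads_total`) or a numeric
#'   vector of per-clone read counts.
#' @return entropy in bits (non-negative).
#' @export
clonal_entropy <- function(x) {
  reads <- if (is.data.frame(x)) x$reads_total else x
  .assert(length(reads) >= 1 && all(reads >= 0) && sum(reads) > 0,
          "need at least one clone with positive reads")
  p <- reads / sum(reads)
  p <- p[p > 0]
  -sum(p * log2(p))
}
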