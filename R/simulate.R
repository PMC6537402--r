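#' Tilt a categorical distribution along a fixed direction
#'
#' Exponentially reweights a categorical distribution: even-indexed
#' categories are multiplied by `exp(strength)`, odd-indexed by
#' `exp(-strength)`, then renormalized. `strength = 0` returns the input;
#' the total-variation distance from the input grows monotonically with
#' `strength`. Used to plant tumor-vs-normal usage shifts.
#'
#' @param prob numeric probability vector (sums to 1).
#' @param strength non-negative tilt strength.
#' @return the tilted probability vector.
#' @export
tilt_categorical <- function(prob, strength) {
  s <- rep_len(c(-1, 1), length(prob))
  p <- prob * exp(strength * s)
  p / sum(p)
}

# default V/J usage: geometric-decay gene frequencies, independent V and J
.default_vj_usage <- function(n_v = 12, n_j = 4, shift = 0) {
  pv <- exp(-0.12 * seq_len(n_v)); pv <- pv / sum(pv)
  pj <- exp(-0.25 * seq_len(n_j)); pj <- pj / sum(pj)
  grid <- expand.grid(v = seq_len(n_v), j = seq_len(n_j))
  prob <- pv[grid$v] * pj[grid$j]
  prob <- tilt_categorical(prob, shift)
  tibble(
    v_call = sprintf("IGHV%02d", grid$v),
    j_call = sprintf("IGHJ%d", grid$j),
    prob = prob
  )
}

# default CDR length triples: unimodal marginals peaked at 8 / 8 / 17;
# shift tilts the L3 marginal
.default_cdrlen_usage <- function(l3_shift = 0) {
  p1 <- c(`6` = 0.05, `7` = 0.2, `8` = 0.5, `9` = 0.2, `10` = 0.05)
  p3 <- c(0.02, 0.05, 0.10, 0.18, 0.30, 0.18, 0.10, 0.05, 0.02)
  names(p3) <- as.character(13:21)
  p3 <- tilt_categorical(p3, l3_shift)
  grid <- expand.grid(L1 = as.integer(names(p1)), L2 = as.integer(names(p1)),
                      L3 = as.integer(names(p3)))
  tibble(
    L1 = grid$L1, L2 = grid$L2, L3 = grid$L3,
    prob = p1[as.character(grid$L1)] * p1[as.character(grid$L2)] *
      p3[as.character(grid$L3)]
  )
}

#' Build a (V, J) usage or CDR-length distribution
#'
#' `vj_usage_profile()` builds the geometric-decay gene-usage table over an
#' `n_v` x `n_j` gene panel, optionally tilted (see [tilt_categorical()]).
#' `cdrlen_profile()` builds the CDR length-triple table with an optional
#' tilt of the CDR3-length marginal. Calibration studies that compare a
#' fitted classifier against [bayes_optimal_auc()] should use a compact
#' panel (few categories) so the patient-averaged likelihood tables are
#' well estimated at moderate cohort sizes.
#'
#' @param n_v,n_j number of V and J genes in the panel.
#' @param shift,l3_shift tilt strength of the tumor distribution.
#' @return a tibble with a `prob` column summing to 1.
#' @export
vj_usage_profile <- function(n_v = 12, n_j = 4, shift = 0) {
  .default_vj_usage(n_v, n_j, shift)
}

#' @rdname vj_usage_profile
#' @export
cdrlen_profile <- function(l3_shift = 0) {
  .default_cdrlen_usage(l3_shift)
}

.check_dist <- function(d, what) {
  .assert(abs(sum(d$prob) - 1) < 1e-9,
          paste0(what, " probabilities must sum to 1"))
}

#' Configuration of the synthetic cohort generator
#'
#' Defines the generative model for paired normal/tumor repertoires with
#' planted, per-channel class differences: (V, J) usage shifts, CDR length
#' shifts, somatic-hypermutation (SHM) count shifts, a position-specific
#' CDR3 amino-acid motif, clone-size skew and cross-tissue contamination.
#' The defaults emulate a mild but realistic tumor effect in every channel;
#' per-channel studies switch individual effects off or up via the shift
#' arguments or by supplying explicit distributions.
#'
#' @param n_patients number of patients (each contributes a normal and a
#'   tumor sample).
#' @param clones_per_tissue clones simulated per tissue sample.
#' @param vj_shift tilt strength separating tumor from normal (V, J) usage
#'   (0 = identical usage).
#' @param cdrlen_shift tilt strength on the tumor CDR3-length marginal.
#' @param shm_normal_mean,shm_tumor_mean named numeric `c(fr=, cdr=)`
#'   Poisson means for SHM counts; the tumor default is below the normal
#'   default (tumor clones are less affinity-matured).
#' @param aa_motif_effect `NULL` for no motif, else
#'   `list(positions=, residue=, prob=)`: at each listed CDR3 position a
#'   tumor clone's germline carries `residue` with probability `prob`
#'   (otherwise, and in normal clones, residues are uniform over the 20
#'   amino acids).
#' @param contamination_rate probability that a clone leaks a fraction of
#'   its reads into the opposite tissue sample.
#' @param read_exponent,read_max discrete power-law (zeta) exponent and
#'   truncation for per-clone read counts; reproduces the dominant-clone /
#'   rare-clone abundance skew.
#' @param read_exponent_tumor optional tumor-specific read exponent (a
#'   smaller value gives more skewed tumor clone sizes, planting a clonal
#'   entropy difference between the tissues); defaults to `read_exponent`.
#' @param variant_lambda Poisson mean for the number of extra CDR3
#'   nucleotide variants per clone beyond the ancestor.
#' @param vj_usage_normal,vj_usage_tumor,cdrlen_normal,cdrlen_tumor
#'   optional explicit categorical distributions (tibbles with a `prob`
#'   column) overriding the shift-based defaults.
#' @param seed integer seed; all randomness in [simulate_cohort()] flows
#'   from it.
#' @return an `effect_config` list.
#' @export
effect_config <- function(n_patients = 10,
                          clones_per_tissue = 100,
                          vj_shift = 0.3,
                          cdrlen_shift = 0.2,
                          shm_normal_mean = c(fr = 8, cdr = 5),
                          shm_tumor_mean = c(fr = 4, cdr = 2.5),
                          aa_motif_effect = list(positions = c(6, 9, 12),
                                                 residue = "W", prob = 0.3),
                          contamination_rate = 0.05,
                          read_exponent = 1.3,
                          read_exponent_tumor = NULL,
                          read_max = 2000,
                          variant_lambda = 1,
                          vj_usage_normal = NULL,
                          vj_usage_tumor = NULL,
                          cdrlen_normal = NULL,
                          cdrlen_tumor = NULL,
                          seed = 1) {
  .assert(n_patients >= 1, "n_patients must be >= 1")
  .assert(clones_per_tissue >= 1, "clones_per_tissue must be >= 1")
  .assert(contamination_rate >= 0 && contamination_rate < 1,
          "contamination_rate must be in [0, 1)")
  cfg <- list(
    n_patients = n_patients,
    clones_per_tissue = clones_per_tissue,
    vj_usage_normal = vj_usage_normal %||% .default_vj_usage(shift = 0),
    vj_usage_tumor = vj_usage_tumor %||% .default_vj_usage(shift = vj_shift),
    cdrlen_normal = cdrlen_normal %||% .default_cdrlen_usage(0),
    cdrlen_tumor = cdrlen_tumor %||% .default_cdrlen_usage(cdrlen_shift),
    shm_normal_mean = shm_normal_mean,
    shm_tumor_mean = shm_tumor_mean,
    aa_motif_effect = aa_motif_effect,
    contamination_rate = contamination_rate,
    read_exponent = read_exponent,
    read_exponent_tumor = read_exponent_tumor %||% read_exponent,
    read_max = read_max,
    variant_lambda = variant_lambda,
    seed = seed
  )
  .check_dist(cfg$vj_usage_normal, "vj_usage_normal")
  .check_dist(cfg$vj_usage_tumor, "vj_usage_tumor")
  .check_dist(cfg$cdrlen_normal, "cdrlen_normal")
  .check_dist(cfg$cdrlen_tumor, "cdrlen_tumor")
  .assert(all(shm_normal_mean >= 0) && all(shm_tumor_mean >= 0),
          "SHM means must be non-negative")
  structure(cfg, class = "effect_config")
}

.aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.nt4 <- c("A", "C", "G", "T")

# one random amino-acid string; tumor CDR3s may carry the planted motif
.random_aa <- function(len, motif = NULL) {
  chars <- sample(.aa20, len, replace = TRUE)
  if (!is.null(motif)) {
    for (p in motif$positions) {
      if (p <= len && stats::runif(1) < motif$prob) chars[p] <- motif$residue
    }
  }
  paste(chars, collapse = "")
}

.rzeta <- function(n, exponent, xmax) {
  x <- seq_len(xmax)
  sample(x, n, replace = TRUE, prob = x^(-exponent))
}

#' Simulate a paired normal/tumor repertoire cohort
#'
#' Generates `n_patients` x 2 tissue samples of clonally structured
#' records. Each clone draws its (V, J) pair, CDR length triple and
#' ancestral sequences from its tissue's distributions, a power-law read
#' count, and a small set of CDR3 nucleotide variants confined to three
#' clone-specific positions — so every pair of clone members satisfies the
#' clonotype criteria (same V/J, same CDR3 length, Hamming distance <= 3).
#' With probability `contamination_rate` a clone leaks a random fraction of
#' its reads into the opposite tissue sample.
#'
#' @param config an [effect_config()].
#' @param seed optional override of `config$seed`.
#' @return a validated repertoire tibble with planted `clone_id` labels;
#'   byte-identical across runs with the same seed.
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  .assert(inherits(config, "effect_config"), "config must be an effect_config")
  withr::local_seed(.subseed(seed, 1))
  rows <- vector("list", config$n_patients * 2L)
  k <- 0L
  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("P%02d", p)
    for (tissue in c("normal", "tumor")) {
      k <- k + 1L
      rows[[k]] <- .simulate_sample(config, pid, tissue)
    }
  }
  out <- dplyr::bind_rows(rows)
  validate_repertoire(out)
  out
}

.simulate_sample <- function(config, pid, tissue) {
  n_cl <- config$clones_per_tissue
  usage <- if (tissue == "tumor") config$vj_usage_tumor else config$vj_usage_normal
  lens <- if (tissue == "tumor") config$cdrlen_tumor else config$cdrlen_normal
  shm <- if (tissue == "tumor") config$shm_tumor_mean else config$shm_normal_mean
  motif <- if (tissue == "tumor") config$aa_motif_effect else NULL
  other <- if (tissue == "tumor") "normal" else "tumor"
  vj_idx <- sample.int(nrow(usage), n_cl, replace = TRUE, prob = usage$prob)
  len_idx <- sample.int(nrow(lens), n_cl, replace = TRUE, prob = lens$prob)
  rexp_t <- if (tissue == "tumor") config$read_exponent_tumor else config$read_exponent
  reads <- .rzeta(n_cl, rexp_t, config$read_max)
  # accumulators (grown per clone, bound once at the end)
  acc <- list()
  add <- function(sequence_id, tis, v_call, j_call, cdr1, cdr2, cdr3_aa,
                  cdr3_nt, dup, shm_fr, shm_cdr, clone_id) {
    acc[[length(acc) + 1]] <<- list(
      sequence_id = sequence_id, patient_id = pid, tissue = tis,
      v_call = v_call, j_call = j_call, cdr1_aa = cdr1, cdr2_aa = cdr2,
      cdr3_aa = cdr3_aa, cdr3 = cdr3_nt, duplicate_count = as.integer(dup),
      shm_fr = shm_fr, shm_cdr = shm_cdr, clone_id = clone_id
    )
  }
  for (cl in seq_len(n_cl)) {
    L1 <- lens$L1[len_idx[cl]]; L2 <- lens$L2[len_idx[cl]]; L3 <- lens$L3[len_idx[cl]]
    cdr1 <- .random_aa(L1); cdr2 <- .random_aa(L2)
    cdr3_aa <- .random_aa(L3, motif)
    nt_len <- 3L * L3
    anc <- sample(.nt4, nt_len, replace = TRUE)
    r_tot <- reads[cl]
    n_var <- min(1L + stats::rpois(1, config$variant_lambda), 4L, r_tot)
    hot <- sample.int(nt_len, min(3L, nt_len))
    variants <- character(n_var)
    variants[1] <- paste(anc, collapse = "")
    if (n_var > 1) {
      for (v in 2:n_var) {
        nt <- anc
        for (h in hot) {
          if (stats::runif(1) < 0.5) nt[h] <- sample(setdiff(.nt4, anc[h]), 1)
        }
        variants[v] <- paste(nt, collapse = "")
      }
    }
    # split reads over variants, ancestor-weighted, each variant >= 1 read
    w <- c(2, rep(1, n_var - 1))
    extra <- if (r_tot > n_var) {
      as.vector(stats::rmultinom(1, r_tot - n_var, w))
    } else rep(0L, n_var)
    dup <- extra + 1L
    clone_id <- sprintf("%s_%s_c%03d", pid, substr(tissue, 1, 1), cl)
    leak_frac <- if (stats::runif(1) < config$contamination_rate) {
      stats::runif(1, 0.05, 0.3)
    } else 0
    for (v in seq_len(n_var)) {
      leak <- if (leak_frac > 0) stats::rbinom(1, dup[v], leak_frac) else 0L
      keep <- dup[v] - leak
      sid <- sprintf("%s_v%d", clone_id, v)
      sfr <- stats::rpois(1, shm[["fr"]]); scd <- stats::rpois(1, shm[["cdr"]])
      if (keep > 0) {
        add(sid, tissue, usage$v_call[vj_idx[cl]], usage$j_call[vj_idx[cl]],
            cdr1, cdr2, cdr3_aa, variants[v], keep, sfr, scd, clone_id)
      }
      if (leak > 0) {
        add(paste0(sid, "_x"), other, usage$v_call[vj_idx[cl]],
            usage$j_call[vj_idx[cl]], cdr1, cdr2, cdr3_aa, variants[v],
            leak, sfr, scd, clone_id)
      }
    }
  }
  cols <- names(acc[[1]])
  as_tibble(stats::setNames(
    lapply(cols, function(cn) unlist(lapply(acc, `[[`, cn), use.names = FALSE)),
    cols
  ))
}

#' Simulate unstructured test sequences
#'
#' Draws i.i.d. annotated sequences (no clonal structure,
#' `duplicate_count = 1`) from the per-tissue channel distributions of a
#' configuration — a large held-out "patient" for measuring per-sequence
#' classifier performance against the analytic optimum.
#'
#' @param config an [effect_config()].
#' @param n_per_tissue sequences per tissue.
#' @param patient_id patient label for the generated records.
#' @param seed integer seed.
#' @return a repertoire tibble of `2 * n_per_tissue` records.
#' @export
simulate_sequences <- function(config, n_per_tissue, patient_id = "HELDOUT",
                               seed = config$seed + 1) {
  .assert(inherits(config, "effect_config"), "config must be an effect_config")
  withr::local_seed(.subseed(seed, 2))
  one_tissue <- function(tissue) {
    usage <- if (tissue == "tumor") config$vj_usage_tumor else config$vj_usage_normal
    lens <- if (tissue == "tumor") config$cdrlen_tumor else config$cdrlen_normal
    shm <- if (tissue == "tumor") config$shm_tumor_mean else config$shm_normal_mean
    motif <- if (tissue == "tumor") config$aa_motif_effect else NULL
    n <- n_per_tissue
    vj <- sample.int(nrow(usage), n, replace = TRUE, prob = usage$prob)
    li <- sample.int(nrow(lens), n, replace = TRUE, prob = lens$prob)
    tibble(
      sequence_id = sprintf("%s_%s_%06d", patient_id, substr(tissue, 1, 1),
                            seq_len(n)),
      patient_id = patient_id, tissue = tissue,
      v_call = usage$v_call[vj], j_call = usage$j_call[vj],
      cdr1_aa = vapply(lens$L1[li], .random_aa, character(1)),
      cdr2_aa = vapply(lens$L2[li], .random_aa, character(1)),
      cdr3_aa = vapply(lens$L3[li], function(L) .random_aa(L, motif),
                       character(1)),
      cdr3 = vapply(3L * lens$L3[li], function(L)
        paste(sample(.nt4, L, replace = TRUE), collapse = ""), character(1)),
      duplicate_count = 1L,
      shm_fr = stats::rpois(n, shm[["fr"]]),
      shm_cdr = stats::rpois(n, shm[["cdr"]]),
      clone_id = NA_character_
    )
  }
  dplyr::bind_rows(one_tissue("normal"), one_tissue("tumor"))
}

#' Category probabilities of a (V, J) or length usage table
#'
#' Collapses a categorical usage tibble into a named probability vector
#' (categories named by pasting the non-`prob` columns), suitable for
#' [bayes_optimal_auc()].
#'
#' @param usage tibble with a `prob` column.
#' @return named numeric vector summing to 1.
#' @export
category_probs <- function(usage) {
  keys <- do.call(paste, c(usage[setdiff(names(usage), "prob")], sep = "|"))
  stats::setNames(usage$prob, keys)
}

#' Exact AUC of the likelihood-ratio classifier
#'
#' For one tumor draw from `p_tumor` and one independent normal draw from
#' `p_normal`, returns the probability that the likelihood ratio
#' `p_tumor / p_normal` ranks the tumor draw above the normal draw, ties
#' counted half — the best achievable per-sequence AUC for that channel,
#' computed exactly by summation over all category pairs.
#'
#' @param p_normal,p_tumor named probability vectors over the same support.
#' @return a number in `[0.5, 1]`.
#' @export
bayes_optimal_auc <- function(p_normal, p_tumor) {
  .assert(length(p_normal) == length(p_tumor) &&
            (is.null(names(p_normal)) || all(names(p_normal) == names(p_tumor))),
          "p_normal and p_tumor must share the same support")
  .assert(abs(sum(p_normal) - 1) < 1e-9 && abs(sum(p_tumor) - 1) < 1e-9,
          "probabilities must each sum to 1")
  lr <- ifelse(p_tumor == 0 & p_normal == 0, 0, p_tumor / p_normal)
  gt <- outer(lr, lr, ">")
  eq <- outer(lr, lr, "==")
  w <- outer(p_tumor, p_normal)
  sum(w * gt) + 0.5 * sum(w * eq)
}
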