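#' Kidera factor table
#'
#' The ten orthogonal physicochemical factors per amino acid, obtained by
#' multivariate analysis of 188 physicochemical properties of the 20
#' residues. The factors are standardized by construction: across the 20
#' residues each factor has approximately zero mean and unit variance.
#'
#' @return a 20 x 10 numeric matrix, rows named by one-letter residue code,
#'   columns `kf1` ... `kf10`.
#' @export
kidera_factors <- function() {
  if (is.null(.kidera_cache$m)) {
    path <- system.file("extdata", "kidera_factors.tsv",
                        package = "bcrclassify", mustWork = TRUE)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    m <- as.matrix(tab[, -1])
    rownames(m) <- tab$residue
    .kidera_cache$m <- m
  }
  .kidera_cache$m
}
.kidera_cache <- new.env(parent = emptyenv())

#' Fix an amino-acid sequence to a target length
#'
#' Trims or pads a CDR sequence to a fixed length. With `mode = "center"`
#' (the default used throughout the pipeline), a too-long sequence has its
#' middle removed, keeping the first `ceiling(target/2)` and last
#' `floor(target/2)` residues; a too-short sequence has pad sentinels
#' (`"-"`, encoded as a zero feature vector) inserted after position
#' `ceiling(len/2)`. With `mode = "ends"` the termini are trimmed/padded
#' instead (the comparison strategy): the N-terminal side keeps or receives
#' the extra position when the count is odd.
#'
#' @param seq a non-empty amino-acid string.
#' @param target target length (positive integer).
#' @param mode `"center"` or `"ends"`.
#' @return a list with `seq` (string of length `target`, pad sentinel `"-"`)
#'   and `pad` (integer positions of inserted sentinels).
#' @export
fix_length <- function(seq, target, mode = c("center", "ends")) {
  mode <- match.arg(mode)
  .assert(is.character(seq) && length(seq) == 1 && nchar(seq) >= 1,
          "seq must be a single non-empty string")
  .assert(target >= 1, "target must be >= 1")
  chars <- strsplit(seq, "")[[1]]
  len <- length(chars)
  if (len == target) {
    return(list(seq = seq, pad = integer(0)))
  }
  if (len > target) {
    d <- len - target
    if (mode == "center") {
      keep_n <- ceiling(target / 2)
      keep_c <- target - keep_n
      out <- c(chars[seq_len(keep_n)], chars[seq.int(len - keep_c + 1, len)])
    } else {
      drop_n <- floor(d / 2)            # N side keeps the extra residue
      drop_c <- d - drop_n
      out <- chars[seq.int(drop_n + 1, len - drop_c)]
    }
    return(list(seq = paste(out, collapse = ""), pad = integer(0)))
  }
  d <- target - len
  if (mode == "center") {
    at <- ceiling(len / 2)
    out <- c(chars[seq_len(at)], rep("-", d),
             if (at < len) chars[seq.int(at + 1, len)])
    pad <- seq.int(at + 1, at + d)
  } else {
    add_n <- ceiling(d / 2)             # N side receives the extra sentinel
    add_c <- d - add_n
    out <- c(rep("-", add_n), chars, rep("-", add_c))
    pad <- c(seq_len(add_n), if (add_c > 0) seq.int(target - add_c + 1, target))
  }
  list(seq = paste(out, collapse = ""), pad = pad)
}

#' Encode CDR sequences as a fixed-size Kidera feature matrix
#'
#' Each CDR is brought to its target length with [fix_length()] and mapped
#' position-wise through the 10-factor Kidera table; the three blocks are
#' stacked in order CDR1, CDR2, CDR3. The pad sentinel and the unknown
#' residue `X` both map to a zero row. With the default targets
#' `c(8, 8, 17)` the result is a 33 x 10 matrix (feature vector length 330).
#'
#' @param cdr1,cdr2,cdr3 non-empty amino-acid strings.
#' @param targets integer vector of three target lengths.
#' @param mode trimming/padding strategy passed to [fix_length()].
#' @return a list with `values` (33 x 10 numeric matrix) and `pad_mask`
#'   (logical, TRUE where a pad sentinel was inserted).
#' @export
kidera_encode <- function(cdr1, cdr2, cdr3, targets = c(8, 8, 17),
                          mode = "center") {
  kf <- kidera_factors()
  one <- function(s, target) {
    fx <- fix_length(s, target, mode)
    chars <- strsplit(fx$seq, "")[[1]]
    bad <- setdiff(chars, c(rownames(kf), "X", "-"))
    .assert(length(bad) == 0,
            paste0("unknown residue(s): ", paste(bad, collapse = ", ")))
    m <- matrix(0, nrow = target, ncol = ncol(kf))
    known <- chars %in% rownames(kf)
    m[known, ] <- kf[chars[known], , drop = FALSE]
    mask <- logical(target)
    mask[fx$pad] <- TRUE
    list(m = m, mask = mask)
  }
  b1 <- one(cdr1, targets[1])
  b2 <- one(cdr2, targets[2])
  b3 <- one(cdr3, targets[3])
  values <- rbind(b1$m, b2$m, b3$m)
  colnames(values) <- colnames(kf)
  list(values = values, pad_mask = c(b1$mask, b2$mask, b3$mask))
}

#' Encode a whole repertoire as a feature matrix
#'
#' Applies [kidera_encode()] to every record and flattens each 33 x 10
#' matrix position-major (position 1 factors 1-10, position 2 factors 1-10,
#' ...) into one row of a numeric matrix.
#'
#' @param records a repertoire tibble.
#' @inheritParams kidera_encode
#' @return a `nrow(records)` x 330 numeric matrix.
#' @export
encode_repertoire <- function(records, targets = c(8, 8, 17),
                              mode = "center") {
  n <- nrow(records)
  out <- matrix(0, nrow = n, ncol = sum(targets) * 10)
  for (i in seq_len(n)) {
    enc <- kidera_encode(records$cdr1_aa[i], records$cdr2_aa[i],
                         records$cdr3_aa[i], targets, mode)
    out[i, ] <- as.vector(t(enc$values))
  }
  rownames(out) <- records$sequence_id
  out
}

#' CDR length triple of each record
#' @param records a repertoire tibble.
#' @return tibble with columns `L1`, `L2`, `L3` (amino-acid lengths).
#' @export
cdr_lengths <- function(records) {
  tibble(L1 = nchar(records$cdr1_aa), L2 = nchar(records$cdr2_aa),
         L3 = nchar(records$cdr3_aa))
}
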