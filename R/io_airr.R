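#' Annotated repertoire records
#'
#' A repertoire is held as a tibble with one row per read-collapsed BCR/Ig
#' heavy-chain sequence. Column names follow the AIRR Rearrangement standard
#' where one exists; `patient_id`, `tissue`, `shm_fr`, `shm_cdr` and
#' `clone_id` are custom columns.
#'
#' @details Required columns:
#' \describe{
#'   \item{sequence_id}{unique identifier of the collapsed sequence}
#'   \item{patient_id}{patient the sample came from}
#'   \item{tissue}{`"normal"` or `"tumor"`}
#'   \item{v_call, j_call}{V and J gene-segment assignments}
#'   \item{cdr1_aa, cdr2_aa, cdr3_aa}{CDR amino-acid sequences (20-letter
#'     alphabet, `X` allowed for unknown residues)}
#'   \item{cdr3}{CDR3 nucleotide sequence (ACGT); length is three times
#'     `nchar(cdr3_aa)`}
#'   \item{duplicate_count}{number of reads supporting the sequence (>= 1)}
#'   \item{shm_fr, shm_cdr}{somatic hypermutation counts in the framework
#'     regions and in the CDRs (>= 0)}
#' }
#' `clone_id` is optional on input and filled by [assign_clonal_families()].
#' Unknown extra columns are preserved on read/write but ignored by the
#' pipeline.
#' @name repertoire-format
NULL

.required_cols <- c(
  "sequence_id", "patient_id", "tissue", "v_call", "j_call",
  "cdr1_aa", "cdr2_aa", "cdr3_aa", "cdr3", "duplicate_count",
  "shm_fr", "shm_cdr"
)

.aa_alphabet <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

#' Validate repertoire records
#'
#' Checks the invariants of the repertoire format (see
#' [repertoire-format]) and fails with the offending row and field named.
#'
#' @param records a repertoire tibble.
#' @return the records, invisibly, if valid.
#' @export
validate_repertoire <- function(records) {
  missing <- setdiff(.required_cols, names(records))
  if (length(missing) > 0) {
    rlang::abort(
      paste0("missing required column(s): ", paste(missing, collapse = ", ")),
      class = "bcrclassify_format_error"
    )
  }
  fail <- function(rows, field, why) {
    if (length(rows) > 0) {
      rlang::abort(
        sprintf("invalid %s at row(s) %s: %s", field,
                paste(utils::head(rows, 5), collapse = ", "), why),
        class = "bcrclassify_validation_error"
      )
    }
  }
  fail(which(!records$tissue %in% c("normal", "tumor")), "tissue",
       "must be 'normal' or 'tumor'")
  fail(which(records$duplicate_count < 1 |
               records$duplicate_count != floor(records$duplicate_count)),
       "duplicate_count", "must be a positive integer")
  fail(which(records$shm_fr < 0), "shm_fr", "must be non-negative")
  fail(which(records$shm_cdr < 0), "shm_cdr", "must be non-negative")
  fail(which(nchar(records$cdr3) != 3L * nchar(records$cdr3_aa)), "cdr3",
       "nucleotide length must be 3 x amino-acid length")
  fail(which(grepl("[^ACGT]", records$cdr3)), "cdr3",
       "must contain only ACGT")
  for (col in c("cdr1_aa", "cdr2_aa", "cdr3_aa")) {
    bad <- which(grepl(sprintf("[^%s]", paste(.aa_alphabet, collapse = "")),
                       records[[col]]))
    fail(bad, col, "contains a character outside the amino-acid alphabet")
  }
  invisible(records)
}

#' Read a repertoire from an AIRR-style TSV file
#'
#' @param path path to a tab-separated file with a header row naming all
#'   required columns (see [repertoire-format]).
#' @return a validated repertoire tibble, one row per data row of the file,
#'   row order preserved.
#' @export
read_repertoire <- function(path) {
  .assert(file.exists(path), paste0("file not found: ", path))
  int_cols <- c("duplicate_count", "shm_fr", "shm_cdr")
  records <- readr::read_tsv(
    path,
    col_types = readr::cols(
      duplicate_count = readr::col_integer(),
      shm_fr = readr::col_integer(),
      shm_cdr = readr::col_integer(),
      .default = readr::col_character()
    ),
    progress = FALSE, na = character()
  )
  missing <- setdiff(.required_cols, names(records))
  if (length(missing) > 0) {
    rlang::abort(
      paste0("missing required column(s): ", paste(missing, collapse = ", ")),
      class = "bcrclassify_format_error"
    )
  }
  if (nrow(records) > 0) validate_repertoire(records)
  records
}

#' Write a repertoire to an AIRR-style TSV file
#'
#' The output is tab-separated, UTF-8, one header row then one row per
#' record, and is inverted exactly by [read_repertoire()].
#'
#' @param records a valid repertoire tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_repertoire <- function(records, path) {
  validate_repertoire(records)
  readr::write_tsv(records, path, progress = FALSE)
  invisible(path)
}
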