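# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

.assert <- function(cond, msg, class = "bcrclassify_error") {
  if (!isTRUE(cond)) rlang::abort(msg, class = class)
}

# fast Mann-Whitney AUC on a 0/1 label vector; NA if one class absent
.auc01 <- function(scores, y01) {
  n_pos <- sum(y01 == 1L)
  n_neg <- sum(y01 == 0L)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[y01 == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# map tissue/class labels to 1 = tumor, 0 = normal
.label01 <- function(labels) {
  lv <- c("normal", "tumor")
  .assert(all(labels %in% lv), "labels must be 'normal' or 'tumor'")
  as.integer(labels == "tumor")
}

# derive a stream-specific 32-bit seed from a master seed
.subseed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647)
}
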