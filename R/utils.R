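# Error conditions carry a class so the CLI can map them to exit codes:
# spanfill_usage_error -> 1, spanfill_validation_error -> 2, spanfill_io_error -> 3.

abort_validation <- function(msg, ...) {
  rlang::abort(msg, class = "spanfill_validation_error", ...)
}

abort_io <- function(msg, ...) {
  rlang::abort(msg, class = "spanfill_io_error", ...)
}

abort_usage <- function(msg, ...) {
  rlang::abort(msg, class = "spanfill_usage_error", ...)
}

#' Reverse-complement a nucleotide string
#'
#' Operates on plain character vectors over `{A,C,G,T,N}`.
#'
#' @param x character vector of sequences.
#' @return character vector of reverse-complemented sequences.
#' @export
#' @examples
#' reverse_complement("ACGTN")
reverse_complement <- function(x) {
  vapply(x, function(s) {
    if (!nzchar(s)) return("")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

# Derive a stage-specific sub-seed from a master seed; kept < 2^31 - 1.
derive_seed <- function(seed, stage) {
  (as.double(seed) * 8 + stage) %% 2147483647
}

# Internal: check a data frame has the given columns.
check_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    abort_validation(sprintf(
      "%s is missing column(s): %s", what, paste(miss, collapse = ", ")
    ))
  }
  invisible(df)
}
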