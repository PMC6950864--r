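#' Parse a CIGAR string into operations
#'
#' @param cigar a single CIGAR string, e.g. `"50S100M2D48M"`.
#' @return tibble with columns `op` (character) and `len` (integer).
#' @export
cigar_ops <- function(cigar) {
  if (is.na(cigar) || !nzchar(cigar) || cigar == "*") {
    abort_validation("missing CIGAR")
  }
  m <- stringr::str_match_all(cigar, "(\\d+)([MIDNSHP=X])")[[1]]
  if (nrow(m) == 0 || sum(nchar(m[, 1])) != nchar(cigar)) {
    abort_validation(sprintf("malformed CIGAR: %s", cigar))
  }
  tibble(op = m[, 3], len = as.integer(m[, 2]))
}

# Per-CIGAR summary used by the parser: reference span, forward-strand read
# interval (H-inclusive), and full read length implied by the CIGAR.
cigar_profile <- function(cigar) {
  ops <- cigar_ops(cigar)
  ref_span <- sum(ops$len[ops$op %in% c("M", "=", "X", "D", "N")])
  read_consumed <- sum(ops$len[ops$op %in% c("M", "=", "X", "I")])
  first_aln <- which(!ops$op %in% c("S", "H"))[1]
  lead_clip <- if (is.na(first_aln) || first_aln == 1L) 0L else sum(ops$len[seq_len(first_aln - 1L)])
  list(
    ref_span = ref_span,
    qstart_fwd = lead_clip,
    qend_fwd = lead_clip + read_consumed,
    read_len = sum(ops$len[ops$op %in% c("M", "=", "X", "I", "S", "H")]),
    has_hard_clip = any(ops$op == "H")
  )
}

#' Read long-read alignments from SAM/BAM
#'
#' Unmapped and secondary records are dropped; supplementary records are kept
#' and, together with their primaries, flagged `is_split_part` whenever a read
#' has two or more mapped parts. All read coordinates are 0-based half-open.
#' `read_start`/`read_end` are on the original-orientation read;
#' `qstart_fwd`/`qend_fwd` are on the reference-forward orientation of the
#' read (the orientation of `seq_fwd`), which is the convention every
#' downstream extraction uses. Hard-clipped parts have their coordinates
#' reconstructed from the `H` counts and their sequence recovered from the
#' read's primary record or from the optional FASTQ side-channel.
#'
#' @param path SAM or BAM file (SAM is converted internally).
#' @param reads optional FASTQ path supplying sequences for records that
#'   carry none (`*` SEQ, or hard-clipped parts without a primary).
#' @return tibble with columns `read_id`, `scaffold`, `ref_start`, `ref_end`,
#'   `read_start`, `read_end`, `qstart_fwd`, `qend_fwd`, `read_len`, `strand`,
#'   `cigar`, `seq_fwd` (reference-forward orientation, full read length),
#'   `is_split_part`, sorted by scaffold then `ref_start`.
#' @export
read_alignments <- function(path, reads = NULL) {
  if (!file.exists(path)) abort_io(sprintf("alignment file not found: %s", path))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- tryCatch(
      Rsamtools::asBam(path, destination = dest, overwrite = TRUE, indexDestination = FALSE),
      error = function(e) abort_io(sprintf("failed to convert SAM '%s': %s", path, conditionMessage(e)))
    )
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag,
    what = c("qname", "flag", "rname", "strand", "pos", "cigar", "seq")
  )
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  if (length(rec$qname) == 0) {
    return(tibble(
      read_id = character(), scaffold = character(), ref_start = integer(),
      ref_end = integer(), read_start = integer(), read_end = integer(),
      qstart_fwd = integer(), qend_fwd = integer(), read_len = integer(),
      strand = character(), cigar = character(), seq_fwd = character(),
      is_split_part = logical()
    ))
  }
  prof <- lapply(rec$cigar, cigar_profile)
  strand <- as.character(rec$strand)
  seq_rec <- as.character(rec$seq)      # record orientation == reference-forward
  has_seq <- !is.na(seq_rec) & nzchar(seq_rec) & seq_rec != "*"
  has_h <- vapply(prof, `[[`, logical(1), "has_hard_clip")

  # Original-orientation read sequences, per read id, from FASTQ and/or the
  # read's own full-length (no hard clip) records.
  orig_seq <- list()
  if (!is.null(reads)) {
    if (!file.exists(reads)) abort_io(sprintf("FASTQ file not found: %s", reads))
    fq <- Biostrings::readDNAStringSet(reads, format = "fastq")
    orig_seq <- as.list(as.character(fq))
    names(orig_seq) <- sub("\\s.*$", "", names(orig_seq))
  }
  full <- which(has_seq & !has_h)
  for (i in full) {
    id <- rec$qname[i]
    if (is.null(orig_seq[[id]])) {
      orig_seq[[id]] <- if (strand[i] == "-") reverse_complement(seq_rec[i]) else seq_rec[i]
    }
  }

  n <- length(rec$qname)
  seq_fwd <- character(n)
  keep <- rep(TRUE, n)
  n_skipped <- 0L
  for (i in seq_len(n)) {
    if (has_seq[i] && !has_h[i]) {
      seq_fwd[i] <- seq_rec[i]
    } else {
      os <- orig_seq[[rec$qname[i]]]
      if (is.null(os)) {
        keep[i] <- FALSE
        n_skipped <- n_skipped + 1L
        next
      }
      seq_fwd[i] <- if (strand[i] == "-") reverse_complement(os) else os
    }
  }
  if (n_skipped > 0) {
    warn(sprintf("%d record(s) without a recoverable sequence skipped", n_skipped))
  }

  read_len <- vapply(prof, `[[`, integer(1), "read_len")
  qstart_fwd <- vapply(prof, `[[`, integer(1), "qstart_fwd")
  qend_fwd <- vapply(prof, `[[`, integer(1), "qend_fwd")
  ref_start <- rec$pos - 1L
  out <- tibble(
    read_id = rec$qname,
    scaffold = as.character(rec$rname),
    ref_start = ref_start,
    ref_end = ref_start + vapply(prof, `[[`, integer(1), "ref_span"),
    read_start = ifelse(strand == "-", read_len - qend_fwd, qstart_fwd),
    read_end = ifelse(strand == "-", read_len - qstart_fwd, qend_fwd),
    qstart_fwd = qstart_fwd,
    qend_fwd = qend_fwd,
    read_len = read_len,
    strand = strand,
    cigar = rec$cigar,
    seq_fwd = seq_fwd,
    is_split_part = FALSE
  )[keep, ]
  out <- out |>
    group_by(.data$read_id) |>
    mutate(is_split_part = n() >= 2) |>
    ungroup() |>
    arrange(.data$scaffold, .data$ref_start)
  out
}

#' Lift a reference coordinate onto the read through a CIGAR
#'
#' Walks the alignment's CIGAR and returns the forward-orientation read
#' coordinate aligned to `ref_pos`. A position inside a deletion maps to the
#' read coordinate immediately after the deletion; `ref_pos == ref_end` maps
#' to the end of the aligned read interval. Positions outside
#' `[ref_start, ref_end]` return `NA`.
#'
#' @param aln one alignment: a list or one-row data frame with at least
#'   `cigar` and `ref_start`.
#' @param ref_pos 0-based reference coordinate(s); vectorised.
#' @return integer read coordinate(s) in forward (reference) orientation of
#'   the read, `NA` where outside the alignment span.
#' @export
liftover_ref_to_read <- function(aln, ref_pos) {
  cigar <- aln$cigar[[1]]
  ref_start <- aln$ref_start[[1]]
  ops <- cigar_ops(cigar)
  vapply(ref_pos, function(p) {
    r <- ref_start
    q <- 0L
    qend_last <- NA_integer_
    if (p < ref_start) return(NA_integer_)
    for (k in seq_len(nrow(ops))) {
      op <- ops$op[k]
      len <- ops$len[k]
      if (op %in% c("S", "H")) {
        q <- q + len
      } else if (op %in% c("M", "=", "X")) {
        if (p < r + len) return(as.integer(q + (p - r)))
        r <- r + len
        q <- q + len
        qend_last <- q
      } else if (op %in% c("D", "N")) {
        if (p < r + len) return(as.integer(q))
        r <- r + len
        qend_last <- q
      } else if (op == "I") {
        q <- q + len
        qend_last <- q
      }
    }
    if (p == r) return(as.integer(qend_last))
    NA_integer_
  }, integer(1))
}
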