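#' Read an assembly FASTA into a tibble
#'
#' Sequences are upper-cased and line wrapping is removed. IUPAC ambiguity
#' codes other than `A`, `C`, `G`, `T`, `N` are coerced to `N` (downstream
#' consensus only ever emits the four bases), with one warning reporting how
#' many characters were coerced.
#'
#' @param path path to a FASTA file.
#' @return a tibble with columns `scaffold` (character), `seq` (character,
#'   upper-case over `{A,C,G,T,N}`) and `length` (integer bp), in file order.
#' @export
read_assembly <- function(path) {
  if (!file.exists(path)) {
    abort_io(sprintf("FASTA file not found: %s", path))
  }
  dss <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) abort_io(sprintf("failed to parse FASTA '%s': %s", path, conditionMessage(e)))
  )
  ids <- sub("\\s.*$", "", names(dss))
  if (anyDuplicated(ids)) {
    abort_validation(sprintf(
      "duplicate scaffold id(s) in %s: %s",
      path, paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  seqs <- toupper(as.character(dss))
  if (any(!nzchar(seqs))) {
    abort_validation(sprintf(
      "empty sequence for scaffold(s): %s", paste(ids[!nzchar(seqs)], collapse = ", ")
    ))
  }
  n_bad <- sum(vapply(
    gregexpr("[^ACGTN]", seqs), function(m) if (m[1] == -1L) 0L else length(m), integer(1)
  ))
  if (n_bad > 0) {
    warn(sprintf("%d non-ACGTN character(s) coerced to N", n_bad))
    seqs <- gsub("[^ACGTN]", "N", seqs)
  }
  tibble(scaffold = ids, seq = unname(seqs), length = unname(nchar(seqs)))
}

#' Write an assembly tibble to FASTA
#'
#' @param assembly tibble with columns `scaffold`, `seq`.
#' @param path output path.
#' @param line_width sequence line width (default 60).
#' @return `path`, invisibly. `read_assembly(write_assembly(x, p))` round-trips
#'   ids and sequences exactly.
#' @export
write_assembly <- function(assembly, path, line_width = 60) {
  check_columns(assembly, c("scaffold", "seq"), "assembly")
  if (nrow(assembly) == 0) abort_validation("refusing to write an empty assembly")
  dss <- Biostrings::DNAStringSet(setNames(assembly$seq, assembly$scaffold))
  tryCatch(
    Biostrings::writeXStringSet(dss, filepath = path, width = line_width),
    error = function(e) abort_io(sprintf("cannot write FASTA '%s': %s", path, conditionMessage(e)))
  )
  invisible(path)
}

#' Locate N-run gaps in an assembly
#'
#' Every maximal run of `N` of length at least `min_gap_length` becomes one
#' gap record; shorter runs are ignored. Coordinates are 0-based, half-open.
#'
#' @param assembly tibble with columns `scaffold`, `seq` (see [read_assembly()]).
#' @param min_gap_length smallest N-run reported as a gap (default 10, the
#'   smallest fixed gap size that linked-read assemblers introduce).
#' @return tibble with columns `gap_id`, `scaffold`, `start`, `end`, `length`,
#'   sorted by scaffold (input order) then `start`. Zero rows when gap-free.
#' @export
find_gaps <- function(assembly, min_gap_length = 10) {
  check_columns(assembly, c("scaffold", "seq"), "assembly")
  if (min_gap_length < 1) abort_validation("min_gap_length must be >= 1")
  pat <- sprintf("N{%d,}", as.integer(min_gap_length))
  rows <- purrr::map2(assembly$scaffold, assembly$seq, function(id, s) {
    m <- gregexpr(pat, s, perl = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    start <- as.integer(m) - 1L                     # to 0-based
    len <- attr(m, "match.length")
    tibble(
      gap_id = sprintf("%s_gap%03d", id, seq_along(start)),
      scaffold = id, start = start, end = start + len, length = len
    )
  })
  out <- list_rbind(purrr::compact(rows))
  if (nrow(out) == 0) {
    return(tibble(
      gap_id = character(), scaffold = character(),
      start = integer(), end = integer(), length = integer()
    ))
  }
  out
}

#' N50 of a length multiset
#'
#' The largest length `L` such that sequences of length `>= L` together cover
#' at least half the total.
#'
#' @param lengths integer vector of sequence lengths.
#' @return integer N50.
#' @export
calc_n50 <- function(lengths) {
  lengths <- as.numeric(lengths)
  if (length(lengths) == 0 || any(lengths <= 0)) {
    abort_validation("calc_n50 needs a non-empty vector of positive lengths")
  }
  s <- sort(lengths, decreasing = TRUE)
  as.integer(s[which(cumsum(s) >= sum(s) / 2)[1]])
}

# Contig lengths of one scaffold: non-empty segments between N-runs of
# length >= break_n. Shorter N-runs stay inside contigs.
contig_lengths <- function(seq, break_n) {
  pieces <- strsplit(seq, sprintf("N{%d,}", as.integer(break_n)), perl = TRUE)[[1]]
  len <- nchar(pieces)
  len[len > 0]
}

#' Assembly continuity statistics
#'
#' Contigs are the non-empty segments obtained by splitting each scaffold at
#' N-runs of length `>= contig_break_n`; scaffold and contig N50 follow the
#' standard definition (see [calc_n50()]).
#'
#' @param assembly tibble with columns `scaffold`, `seq`.
#' @param contig_break_n N-run length at which a scaffold is broken into
#'   contigs (default 10).
#' @param min_gap_length passed to [find_gaps()] for the `n_gaps` count.
#' @return one-row tibble: `n_scaffolds`, `n_contigs`, `total_bp`, `total_N`,
#'   `scaffold_n50`, `contig_n50`, `mean_contig`, `n_gaps`.
#' @export
assembly_stats <- function(assembly, contig_break_n = 10, min_gap_length = contig_break_n) {
  check_columns(assembly, c("scaffold", "seq"), "assembly")
  if (nrow(assembly) == 0) abort_validation("empty assembly")
  scaf_len <- nchar(assembly$seq)
  contigs <- unlist(lapply(assembly$seq, contig_lengths, break_n = contig_break_n))
  total_N <- sum(stringr::str_count(assembly$seq, "N"))
  tibble(
    n_scaffolds = nrow(assembly),
    n_contigs = length(contigs),
    total_bp = sum(scaf_len),
    total_N = total_N,
    scaffold_n50 = calc_n50(scaf_len),
    contig_n50 = calc_n50(contigs),
    mean_contig = as.integer(floor(sum(contigs) / length(contigs))),
    n_gaps = nrow(find_gaps(assembly, min_gap_length = min_gap_length))
  )
}

#' Extract the non-N reference flanks of a gap
#'
#' Returns up to `flank` bp of assembly sequence immediately left and right of
#' the gap, truncated at scaffold ends and at neighbouring N-runs so the
#' flanks never contain `N`.
#'
#' @param seq scaffold sequence.
#' @param start,end 0-based half-open gap interval.
#' @param flank maximum flank width (default 50).
#' @return list with elements `left` and `right` (character).
#' @export
gap_flanks <- function(seq, start, end, flank = 50) {
  left <- substr(seq, max(1, start - flank + 1), start)
  right <- substr(seq, end + 1, min(nchar(seq), end + flank))
  # trim back to the nearest N so flanks are pure contig sequence
  left <- sub("^.*N", "", left)
  right <- sub("N.*$", "", right)
  list(left = left, right = right)
}
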