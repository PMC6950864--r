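# Substitution matrix over {A,C,G,T,N}: match +1, everything involving N or a
# mismatch -1. Consensus never emits N, so N earns no reward anywhere.
sub_matrix <- function(match = 1, mismatch = -1) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- match
  m["N", "N"] <- mismatch
  m
}

# Global (Needleman-Wunsch, affine) pairwise alignment of two sequences.
# Returns list(a, b) of equal-length aligned strings. A gap of length L costs
# gap_open + L * gap_extend.
pw_align <- function(a, b, match = 1, mismatch = -1, gap_open = 2, gap_extend = 1) {
  al <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b,
    substitutionMatrix = sub_matrix(match, mismatch),
    gapOpening = gap_open, gapExtension = gap_extend, type = "global"
  )
  list(
    a = as.character(Biostrings::alignedPattern(al)),
    b = as.character(Biostrings::alignedSubject(al)),
    score = Biostrings::score(al)
  )
}

pw_score <- function(a, b, match = 1, mismatch = -1, gap_open = 2, gap_extend = 1) {
  Biostrings::pairwiseAlignment(
    pattern = a, subject = b,
    substitutionMatrix = sub_matrix(match, mismatch),
    gapOpening = gap_open, gapExtension = gap_extend, type = "global",
    scoreOnly = TRUE
  )
}

#' Center-star multiple sequence alignment
#'
#' Picks the sequence with the maximal summed pairwise alignment score
#' against all others as the center (ties broken by lowest input index),
#' aligns every other sequence to it globally (match +1, mismatch -1, gap
#' open -2, gap extend -1), and merges the pairwise alignments under the
#' "once a gap, always a gap" rule. Deterministic for fixed inputs.
#'
#' @param seqs character vector of at least two non-empty sequences.
#' @param match,mismatch,gap_open,gap_extend alignment scores; penalties are
#'   given as positive magnitudes.
#' @return character vector of equal-length aligned rows over
#'   `{A,C,G,T,N,-}`; removing `-` from row i reproduces `seqs[i]`.
#' @export
build_msa <- function(seqs, match = 1, mismatch = -1, gap_open = 2, gap_extend = 1) {
  k <- length(seqs)
  if (k < 2) abort_validation("build_msa needs at least 2 sequences (use the single-read fallback)")
  if (any(!nzchar(seqs))) abort_validation("build_msa: empty sequence")
  if (length(unique(seqs)) == 1) {
    return(rep(seqs[1], k))          # identical inputs need no gaps
  }
  # Center selection: summed pairwise score, lowest index wins ties.
  if (k == 2) {
    center <- 1L
  } else {
    scores <- matrix(0, k, k)
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        s <- if (seqs[i] == seqs[j]) nchar(seqs[i]) * match else
          pw_score(seqs[i], seqs[j], match, mismatch, gap_open, gap_extend)
        scores[i, j] <- s
        scores[j, i] <- s
      }
    }
    center <- which.max(rowSums(scores))
  }
  others <- setdiff(seq_len(k), center)
  c_len <- nchar(seqs[center])
  # For each non-center row: aligned-to-center strings; ins[j] counts row
  # characters falling between center positions j-1 and j (slot j, 1..c_len+1).
  alns <- lapply(others, function(i) {
    if (seqs[i] == seqs[center]) {
      list(a = seqs[i], b = seqs[center])
    } else {
      pw_align(seqs[i], seqs[center], match, mismatch, gap_open, gap_extend)
    }
  })
  ins <- lapply(alns, function(al) {
    bc <- strsplit(al$b, "")[[1]]
    # slot index for every alignment column: cumsum of non-gap center chars + 1
    slot <- cumsum(bc != "-") + ifelse(bc != "-", 0L, 1L)
    slot[bc != "-"] <- NA          # center-consuming columns are not insertions
    tabulate(slot[!is.na(slot)], nbins = c_len + 1L)
  })
  master <- do.call(pmax, c(ins, list(rep(0L, c_len + 1L))))
  width <- c_len + sum(master)
  pad <- function(chars_per_slot) {
    # chars_per_slot: list of character vectors, slots 1..c_len+1 interleaved
    # with center columns; pad each slot to master width with '-'.
    out <- character(0)
    for (j in seq_len(c_len + 1L)) {
      cs <- chars_per_slot$slots[[j]]
      out <- c(out, cs, rep("-", master[j] - length(cs)))
      if (j <= c_len) out <- c(out, chars_per_slot$cols[j])
    }
    paste(out, collapse = "")
  }
  rows <- character(k)
  rows[center] <- pad(list(
    slots = rep(list(character(0)), c_len + 1L),
    cols = strsplit(seqs[center], "")[[1]]
  ))
  for (m in seq_along(others)) {
    al <- alns[[m]]
    ac <- strsplit(al$a, "")[[1]]
    bc <- strsplit(al$b, "")[[1]]
    ctr_idx <- cumsum(bc != "-")
    slots <- rep(list(character(0)), c_len + 1L)
    cols <- rep("-", c_len)
    for (t in seq_along(bc)) {
      if (bc[t] == "-") {
        j <- ctr_idx[t] + 1L
        slots[[j]] <- c(slots[[j]], ac[t])
      } else {
        cols[ctr_idx[t]] <- ac[t]
      }
    }
    rows[others[m]] <- pad(list(slots = slots, cols = cols))
  }
  stopifnot(all(nchar(rows) == width))
  rows
}

#' Majority consensus with tie-column removal
#'
#' Per column, the symbols `{A,C,G,T,N,-}` are tallied; leading and trailing
#' gaps of each row are treated as missing data and do not vote. A strict
#' plurality base is emitted; a plurality gap emits nothing; a tie for the
#' top count emits nothing, and counts toward `n_dropped_columns` when at
#' least two of the tied symbols are bases (base-vs-gap ties are treated
#' like plurality gaps).
#'
#' @param msa_rows equal-length aligned rows (see [build_msa()]).
#' @return list with `consensus_seq` (character) and `n_dropped_columns`
#'   (integer).
#' @export
call_consensus <- function(msa_rows) {
  if (length(msa_rows) == 0) abort_validation("call_consensus: empty MSA")
  w <- unique(nchar(msa_rows))
  if (length(w) != 1) abort_validation("call_consensus: rows differ in length")
  mat <- do.call(rbind, strsplit(msa_rows, ""))
  # mask terminal gaps row-wise
  for (i in seq_len(nrow(mat))) {
    nz <- which(mat[i, ] != "-")
    if (length(nz) == 0) { mat[i, ] <- NA_character_; next }
    if (nz[1] > 1) mat[i, seq_len(nz[1] - 1)] <- NA_character_
    if (nz[length(nz)] < w) mat[i, seq(nz[length(nz)] + 1, w)] <- NA_character_
  }
  out <- character(0)
  n_dropped <- 0L
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    col <- col[!is.na(col)]
    if (length(col) == 0) next
    tab <- table(col)
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1) {
      if (top != "-") out <- c(out, top)
    } else if (sum(top != "-") >= 2) {
      n_dropped <- n_dropped + 1L        # base-vs-base tie: column removed
    }
  }
  list(consensus_seq = paste(out, collapse = ""), n_dropped_columns = n_dropped)
}
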