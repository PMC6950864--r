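empty_evidence <- function() {
  tibble(
    gap_id = character(), read_id = character(), pathway = character(),
    extracted_seq = character(), left_anchor_bp = integer(), right_anchor_bp = integer()
  )
}

#' Unsplit spanning evidence for gaps
#'
#' A non-split alignment qualifies for a gap when it covers the gap plus at
#' least `flank` aligned bp on each side (`ref_start <= gap_start - flank`
#' and `ref_end >= gap_end + flank`, both inclusive). The extracted sequence
#' is the read subsequence between the liftovers of `gap_start - flank` and
#' `gap_end + flank`, so it carries read-derived flanks.
#'
#' @param alignments tibble from [read_alignments()].
#' @param gaps tibble from [find_gaps()] (any subset of its rows).
#' @param flank required anchoring width in bp (default 50).
#' @return evidence tibble: `gap_id`, `read_id`, `pathway` (`"unsplit"`),
#'   `extracted_seq` (reference orientation), `left_anchor_bp`,
#'   `right_anchor_bp`. Zero rows when nothing qualifies.
#' @export
unsplit_spanning <- function(alignments, gaps, flank = 50) {
  check_columns(alignments, c("read_id", "scaffold", "ref_start", "ref_end",
                              "cigar", "seq_fwd", "is_split_part"), "alignments")
  check_columns(gaps, c("gap_id", "scaffold", "start", "end"), "gaps")
  un <- filter(alignments, !.data$is_split_part)
  if (nrow(un) == 0 || nrow(gaps) == 0) return(empty_evidence())
  rows <- purrr::pmap(gaps[c("gap_id", "scaffold", "start", "end")],
    function(gap_id, scaffold, start, end) {
      cand <- un[un$scaffold == scaffold &
                   un$ref_start <= start - flank &
                   un$ref_end >= end + flank, ]
      if (nrow(cand) == 0) return(NULL)
      ex <- vapply(seq_len(nrow(cand)), function(i) {
        a <- cand[i, ]
        q1 <- liftover_ref_to_read(a, start - flank)
        q2 <- liftover_ref_to_read(a, end + flank)
        substr(a$seq_fwd, q1 + 1L, q2)
      }, character(1))
      tibble(
        gap_id = gap_id, read_id = cand$read_id, pathway = "unsplit",
        extracted_seq = ex,
        left_anchor_bp = as.integer(start - cand$ref_start),
        right_anchor_bp = as.integer(cand$ref_end - end)
      )
    })
  out <- list_rbind(purrr::compact(rows))
  if (nrow(out) == 0) empty_evidence() else out
}

#' Split-read spanning evidence for large gaps
#'
#' Only gaps of length `>= min_split_gap` are considered. A split group (all
#' mapped parts of one read on one scaffold) qualifies when exactly one part
#' ends within `max_side_dist` bp left of the gap start, exactly one part
#' starts within `max_side_dist` bp right of the gap end, both on the same
#' strand and in consistent read order. The extracted sequence is the read
#' interval strictly between the two mapped parts (possibly empty), reported
#' in reference orientation. Groups with more than two candidate parts around
#' one gap are skipped with a warning.
#'
#' @inheritParams unsplit_spanning
#' @param min_split_gap smallest gap handled by this pathway (default 3000).
#' @param max_side_dist how close a part's end must map to the gap edge
#'   (default 100 bp).
#' @return evidence tibble as in [unsplit_spanning()], `pathway` = `"split"`.
#' @export
split_spanning <- function(alignments, gaps, min_split_gap = 3000, max_side_dist = 100) {
  check_columns(alignments, c("read_id", "scaffold", "ref_start", "ref_end",
                              "qstart_fwd", "qend_fwd", "strand", "seq_fwd",
                              "is_split_part"), "alignments")
  sp <- filter(alignments, .data$is_split_part)
  big <- filter(gaps, .data$length >= min_split_gap)
  if (nrow(sp) == 0 || nrow(big) == 0) return(empty_evidence())
  n_ambig <- 0L
  rows <- purrr::pmap(big[c("gap_id", "scaffold", "start", "end")],
    function(gap_id, scaffold, start, end) {
      near <- sp[sp$scaffold == scaffold, ]
      if (nrow(near) == 0) return(NULL)
      is_a <- near$ref_end >= start - max_side_dist & near$ref_end <= start
      is_b <- near$ref_start >= end & near$ref_start <= end + max_side_dist
      cand <- near[is_a | is_b, ]
      if (nrow(cand) == 0) return(NULL)
      out <- lapply(split(seq_len(nrow(cand)), cand$read_id), function(idx) {
        grp <- cand[idx, ]
        if (nrow(grp) > 2) {
          n_ambig <<- n_ambig + 1L
          return(NULL)
        }
        a <- grp[grp$ref_end >= start - max_side_dist & grp$ref_end <= start, ]
        b <- grp[grp$ref_start >= end & grp$ref_start <= end + max_side_dist, ]
        if (nrow(a) != 1 || nrow(b) != 1 || a$read_id != b$read_id) return(NULL)
        if (identical(a$cigar, b$cigar) && a$ref_start == b$ref_start) return(NULL)
        if (a$strand != b$strand) return(NULL)
        if (a$qend_fwd > b$qstart_fwd) return(NULL)  # inconsistent read order
        tibble(
          gap_id = gap_id, read_id = a$read_id, pathway = "split",
          extracted_seq = substr(a$seq_fwd, a$qend_fwd + 1L, b$qstart_fwd),
          left_anchor_bp = as.integer(a$ref_end - a$ref_start),
          right_anchor_bp = as.integer(b$ref_end - b$ref_start)
        )
      })
      list_rbind(purrr::compact(unname(out)))
    })
  if (n_ambig > 0) {
    warn(sprintf("%d split group(s) with >2 candidate parts around a gap skipped", n_ambig))
  }
  out <- list_rbind(purrr::compact(rows))
  if (nrow(out) == 0) empty_evidence() else out
}

#' Collect all spanning evidence for a set of gaps
#'
#' Runs both pathways and resolves duplicates: when one read yields both
#' unsplit and split evidence for the same gap, the unsplit evidence wins and
#' the split record is discarded with a warning.
#'
#' @inheritParams split_spanning
#' @param flank anchoring width for the unsplit pathway (default 50).
#' @return combined evidence tibble.
#' @export
gap_evidence <- function(alignments, gaps, flank = 50, min_split_gap = 3000,
                         max_side_dist = 100) {
  ev <- bind_rows(
    unsplit_spanning(alignments, gaps, flank = flank),
    split_spanning(alignments, gaps, min_split_gap = min_split_gap,
                   max_side_dist = max_side_dist)
  )
  if (nrow(ev) == 0) return(empty_evidence())
  dup <- duplicated(ev[c("gap_id", "read_id")])
  if (any(dup)) {
    warn(sprintf(
      "%d split evidence record(s) discarded in favour of unsplit evidence from the same read",
      sum(dup)
    ))
    ev <- ev[!dup, ]
  }
  ev
}
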