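#' Classify a gap length against the fixed assembler gap sizes
#'
#' Linked-read assemblers introduce gaps of fixed nominal sizes
#' (10/100/400 bp, and 3000/5000/10000 bp). A length within 10% of a nominal
#' size is binned with it; 10-400 bp sizes form the `"small"` class closed by
#' unsplit reads, 3-10 kb sizes the `"large"` class closed by split reads.
#'
#' @param length integer vector of gap lengths.
#' @param tol relative tolerance for matching a nominal size (default 0.1).
#' @return character vector: `"small"`, `"large"` or `"other"`.
#' @export
gap_size_class <- function(length, tol = 0.1) {
  nominal <- c(10, 100, 400, 3000, 5000, 10000)
  vapply(length, function(l) {
    hit <- nominal[abs(l - nominal) <= tol * nominal]
    if (length(hit) == 0) "other" else if (hit[1] <= 400) "small" else "large"
  }, character(1))
}

#' Decide the patch for one gap from its pooled evidence
#'
#' With no evidence the gap stays `uncovered`. With one read the raw
#' extracted sequence is used (single-read fallback): as-is for the unsplit
#' pathway (its flanks are read-derived), or wrapped in the reference flanks
#' for the split pathway. With two or more reads a center-star MSA is built
#' and the tie-dropping majority consensus becomes the replacement; the
#' reference flanks participate per pathway - as separate anchor rows for
#' unsplit evidence, concatenated onto each unmapped middle for split
#' evidence. A consensus shorter than the flanks plus one base means the
#' evidence failed to resolve the gap: status `ambiguous`.
#'
#' @param gap one gap: list or one-row tibble with `gap_id`, `scaffold`,
#'   `start`, `end`.
#' @param evidence evidence tibble rows for this gap (see [gap_evidence()]).
#' @param ref_flank_left,ref_flank_right up to 50 bp of non-N assembly
#'   sequence adjacent to the gap (see [gap_flanks()]).
#' @inheritParams build_msa
#' @return one-row tibble: `gap_id`, `scaffold`, `replace_start`,
#'   `replace_end` (0-based half-open on the pre-patch scaffold),
#'   `replacement_seq`, `status` (`closed`/`uncovered`/`ambiguous`),
#'   `coverage`, `pathway`, `used_fallback`, `n_dropped_columns`.
#' @export
close_gap <- function(gap, evidence, ref_flank_left, ref_flank_right,
                      match = 1, mismatch = -1, gap_open = 2, gap_extend = 1) {
  lw <- nchar(ref_flank_left)
  rw <- nchar(ref_flank_right)
  res <- tibble(
    gap_id = gap$gap_id[[1]], scaffold = gap$scaffold[[1]],
    replace_start = as.integer(gap$start[[1]] - lw),
    replace_end = as.integer(gap$end[[1]] + rw),
    replacement_seq = "", status = "uncovered",
    coverage = nrow(evidence), pathway = NA_character_,
    used_fallback = FALSE, n_dropped_columns = 0L
  )
  if (nrow(evidence) == 0) return(res)
  if (length(unique(evidence$pathway)) > 1) {
    warn(sprintf("gap %s: mixed-pathway evidence; keeping unsplit reads only", res$gap_id))
    evidence <- filter(evidence, .data$pathway == "unsplit")
  }
  pathway <- evidence$pathway[1]
  res$pathway <- pathway
  rows <- if (pathway == "split") {
    paste0(ref_flank_left, evidence$extracted_seq, ref_flank_right)
  } else {
    evidence$extracted_seq
  }
  if (nrow(evidence) == 1) {
    res$replacement_seq <- rows[1]
    res$status <- "closed"
    res$used_fallback <- TRUE
    return(res)
  }
  if (pathway == "unsplit") {
    rows <- c(rows, ref_flank_left, ref_flank_right)   # flank anchor rows
  }
  msa <- build_msa(rows, match, mismatch, gap_open, gap_extend)
  cons <- call_consensus(msa)
  res$n_dropped_columns <- cons$n_dropped_columns
  if (nchar(cons$consensus_seq) < lw + rw + 1) {
    res$status <- "ambiguous"
    return(res)
  }
  res$replacement_seq <- cons$consensus_seq
  res$status <- "closed"
  res
}

#' Close every gap of an assembly from pooled evidence
#'
#' @param assembly assembly tibble (see [read_assembly()]).
#' @param gaps gap tibble (see [find_gaps()]).
#' @param evidence evidence tibble (see [gap_evidence()]).
#' @param flank reference flank width added around each gap (default 50).
#' @inheritParams build_msa
#' @return tibble of patch actions, one row per gap (see [close_gap()]).
#' @export
close_gaps <- function(assembly, gaps, evidence, flank = 50,
                       match = 1, mismatch = -1, gap_open = 2, gap_extend = 1) {
  check_columns(gaps, c("gap_id", "scaffold", "start", "end", "length"), "gaps")
  if (nrow(gaps) == 0) {
    return(tibble(
      gap_id = character(), scaffold = character(), replace_start = integer(),
      replace_end = integer(), replacement_seq = character(),
      status = character(), coverage = integer(), pathway = character(),
      used_fallback = logical(), n_dropped_columns = integer()
    ))
  }
  seqs <- setNames(assembly$seq, assembly$scaffold)
  ev_by_gap <- split(evidence, evidence$gap_id)
  rows <- purrr::map(seq_len(nrow(gaps)), function(i) {
    g <- gaps[i, ]
    fl <- gap_flanks(seqs[[g$scaffold]], g$start, g$end, flank = flank)
    close_gap(g, ev_by_gap[[g$gap_id]] %||% empty_evidence(),
              fl$left, fl$right, match, mismatch, gap_open, gap_extend)
  })
  list_rbind(rows)
}

#' Apply patch actions to an assembly
#'
#' Closed actions are applied right to left within each scaffold so earlier
#' coordinates stay valid; the output differs from the input only inside the
#' replaced intervals. Returns a `gap_closure` object; use [tidy()] for the
#' per-gap report and [glance()] for the run summary.
#'
#' @param assembly assembly tibble (pre-patch).
#' @param actions patch-action tibble from [close_gaps()].
#' @param gaps optional gap tibble (adds gap length/class to the report).
#' @param contig_break_n passed to [assembly_stats()].
#' @return object of class `gap_closure`: list with `assembly` (patched
#'   tibble), `actions`, `report`, `pre_stats`, `post_stats`.
#' @export
patch_assembly <- function(assembly, actions, gaps = NULL, contig_break_n = 10) {
  check_columns(actions, c("gap_id", "scaffold", "replace_start", "replace_end",
                           "replacement_seq", "status", "coverage"), "actions")
  closed <- filter(actions, .data$status == "closed")
  if (nrow(closed) > 0) {
    by_scaf <- split(closed, closed$scaffold)
    for (sc in names(by_scaf)) {
      a <- arrange(by_scaf[[sc]], .data$replace_start)
      if (nrow(a) > 1 && any(a$replace_start[-1] < a$replace_end[-nrow(a)])) {
        abort_validation(sprintf("overlapping replace intervals on scaffold %s", sc))
      }
    }
  }
  patched <- assembly
  if (nrow(closed) > 0) {
    idx <- match(closed$scaffold, patched$scaffold)
    if (anyNA(idx)) abort_validation("action references unknown scaffold")
    for (sc in unique(closed$scaffold)) {
      acts <- arrange(filter(closed, .data$scaffold == sc), desc(.data$replace_start))
      s <- patched$seq[patched$scaffold == sc]
      for (i in seq_len(nrow(acts))) {
        s <- paste0(
          substr(s, 1, acts$replace_start[i]),
          acts$replacement_seq[i],
          substr(s, acts$replace_end[i] + 1L, nchar(s))
        )
      }
      patched$seq[patched$scaffold == sc] <- s
    }
    patched$length <- nchar(patched$seq)
  }
  report <- actions |>
    mutate(
      old_len = .data$replace_end - .data$replace_start,
      new_len = ifelse(.data$status == "closed", nchar(.data$replacement_seq), NA_integer_)
    )
  if (!is.null(gaps)) {
    report <- left_join(report, select(gaps, "gap_id", gap_length = "length"), by = "gap_id") |>
      mutate(class = gap_size_class(.data$gap_length))
  } else {
    report$gap_length <- NA_integer_
    report$class <- NA_character_
  }
  structure(
    list(
      assembly = patched, actions = actions, report = report,
      pre_stats = assembly_stats(assembly, contig_break_n = contig_break_n),
      post_stats = assembly_stats(patched, contig_break_n = contig_break_n)
    ),
    class = "gap_closure"
  )
}

#' Run the whole closure pipeline on one assembly
#'
#' Convenience wrapper: find gaps, collect evidence from alignments, pool and
#' close, patch. Equivalent to calling [find_gaps()], [gap_evidence()],
#' [close_gaps()] and [patch_assembly()] in sequence.
#'
#' @param assembly assembly tibble.
#' @param alignments alignment tibble from [read_alignments()].
#' @param min_gap_length smallest N-run treated as a gap (default 10).
#' @param flank anchoring / reference flank width (default 50).
#' @param min_split_gap smallest gap handled by the split pathway (default 3000).
#' @param max_side_dist split-part distance tolerance (default 100).
#' @param contig_break_n N-run length that breaks contigs in the stats.
#' @return a `gap_closure` object (see [patch_assembly()]).
#' @export
close_assembly_gaps <- function(assembly, alignments, min_gap_length = 10,
                                flank = 50, min_split_gap = 3000,
                                max_side_dist = 100, contig_break_n = 10) {
  gaps <- find_gaps(assembly, min_gap_length = min_gap_length)
  ev <- gap_evidence(alignments, gaps, flank = flank,
                     min_split_gap = min_split_gap, max_side_dist = max_side_dist)
  actions <- close_gaps(assembly, gaps, ev, flank = flank)
  patch_assembly(assembly, actions, gaps = gaps, contig_break_n = contig_break_n)
}

#' @exportS3Method base::print
print.gap_closure <- function(x, ...) {
  g <- glance(x)
  cat("Gap closure:", g$n_closed, "of", g$n_gaps, "gaps closed",
      sprintf("(%d uncovered, %d ambiguous)\n", g$n_uncovered, g$n_ambiguous))
  cat(sprintf("  contig N50 %d -> %d bp; total N %d -> %d; bp change %+d\n",
              g$contig_n50_pre, g$contig_n50_post, g$total_N_pre, g$total_N_post,
              g$bp_change))
  invisible(x)
}

#' Per-gap closure report
#'
#' @param x a `gap_closure` object.
#' @param ... unused.
#' @return tibble with one row per gap: `gap_id`, `scaffold`, `class`,
#'   `status`, `pathway`, `coverage`, `old_len`, `new_len`.
#' @export
tidy.gap_closure <- function(x, ...) {
  select(x$report, "gap_id", "scaffold", "class", "status", "pathway",
         "coverage", "old_len", "new_len")
}

#' One-row closure run summary
#'
#' @param x a `gap_closure` object.
#' @param ... unused.
#' @return one-row tibble with closure counts by status and size class, mean
#'   coverage over closed gaps, scaffolds touched, bp change, and pre/post
#'   continuity statistics.
#' @export
glance.gap_closure <- function(x, ...) {
  r <- x$report
  cl <- filter(r, .data$status == "closed")
  tibble(
    n_gaps = nrow(r),
    n_closed = nrow(cl),
    n_uncovered = sum(r$status == "uncovered"),
    n_ambiguous = sum(r$status == "ambiguous"),
    closed_small = sum(cl$class == "small", na.rm = TRUE),
    closed_large = sum(cl$class == "large", na.rm = TRUE),
    mean_coverage_closed = if (nrow(cl)) mean(cl$coverage) else NA_real_,
    scaffolds_touched = length(unique(cl$scaffold)),
    bp_change = if (nrow(cl)) sum(cl$new_len - cl$old_len) else 0L,
    total_N_pre = x$pre_stats$total_N, total_N_post = x$post_stats$total_N,
    contig_n50_pre = x$pre_stats$contig_n50, contig_n50_post = x$post_stats$contig_n50,
    mean_contig_pre = x$pre_stats$mean_contig, mean_contig_post = x$post_stats$mean_contig
  )
}

#' Percent identity of two sequences under global alignment
#'
#' Matches divided by alignment length (gaps included), as a fraction in
#' `[0, 1]`. Used to score patched regions against a truth genome.
#'
#' @param a,b nucleotide strings.
#' @return numeric identity fraction.
#' @export
alignment_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) return(0)
  if (a == b) return(1)
  al <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, substitutionMatrix = sub_matrix(),
    gapOpening = 2, gapExtension = 1, type = "global"
  )
  Biostrings::pid(al, type = "PID1") / 100
}
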