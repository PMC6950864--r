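# Independent brute-force oracles and tiny fixture builders used across the
# suite. Each oracle is deliberately coded on a different path from the
# package implementation it checks.

# N50 by direct definition: the largest length L in the multiset such that
# the lengths >= L sum to at least half the total.
n50_oracle <- function(lengths) {
  total <- sum(lengths)
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand) {
    if (sum(lengths[lengths >= L]) >= total / 2) return(L)
  }
  stop("unreachable")
}

# Per-base CIGAR expansion: read coordinate (forward orientation) aligned to
# every reference position in [ref_start, ref_end], deletion positions
# mapping to the read coordinate immediately after the deletion, and
# ref_end mapping to the end of the aligned read interval.
liftover_oracle <- function(cigar, ref_start) {
  m <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(sub("[A-Z=]$", "", m))
  ops <- sub("^\\d+", "", m)
  q <- 0L
  r <- ref_start
  ref_pos <- integer(0)
  read_coord <- integer(0)
  q_end <- NA_integer_
  for (k in seq_along(ops)) {
    if (ops[k] %in% c("S", "H")) {
      q <- q + lens[k]
    } else if (ops[k] %in% c("M", "=", "X")) {
      for (b in seq_len(lens[k])) {
        ref_pos <- c(ref_pos, r)
        read_coord <- c(read_coord, q)
        r <- r + 1L
        q <- q + 1L
      }
      q_end <- q
    } else if (ops[k] %in% c("D", "N")) {
      for (b in seq_len(lens[k])) {
        ref_pos <- c(ref_pos, r)
        read_coord <- c(read_coord, q)
        r <- r + 1L
      }
      q_end <- q
    } else if (ops[k] == "I") {
      q <- q + lens[k]
      q_end <- q
    }
  }
  # (at a D op, q is already the coordinate of the next aligned read base,
  # i.e. the coordinate immediately after the deletion)
  data.frame(ref_pos = c(ref_pos, r), read_coord = c(read_coord, q_end))
}

# Random valid CIGAR whose aligned part starts and ends with M.
random_cigar <- function() {
  parts <- character(0)
  if (runif(1) < 0.4) parts <- c(parts, paste0(sample(1:40, 1), sample(c("S", "H"), 1)))
  n_blocks <- sample(1:6, 1)
  for (b in seq_len(n_blocks)) {
    parts <- c(parts, paste0(sample(1:30, 1), "M"))
    if (b < n_blocks) parts <- c(parts, paste0(sample(1:10, 1), sample(c("I", "D"), 1)))
  }
  if (runif(1) < 0.4) parts <- c(parts, paste0(sample(1:40, 1), "S"))
  paste(parts, collapse = "")
}

# Per-column tally consensus with terminal gaps as missing data; independent
# of the package's matrix-based implementation.
consensus_oracle <- function(rows) {
  width <- nchar(rows[1])
  votes <- lapply(rows, function(r) {
    ch <- strsplit(r, "")[[1]]
    lead <- regmatches(r, regexpr("^-*", r))
    trail <- regmatches(r, regexpr("-*$", r))
    mask <- rep(FALSE, width)
    if (nchar(lead) > 0) mask[seq_len(nchar(lead))] <- TRUE
    if (nchar(trail) > 0 && nchar(trail) < width) {
      mask[(width - nchar(trail) + 1):width] <- TRUE
    } else if (nchar(trail) == width) {
      mask[] <- TRUE
    }
    ch[mask] <- NA
    ch
  })
  out <- character(0)
  dropped <- 0L
  for (j in seq_len(width)) {
    col <- vapply(votes, `[[`, character(1), j)
    col <- col[!is.na(col)]
    if (length(col) == 0) next
    cnt <- sort(table(col), decreasing = TRUE)
    winners <- names(cnt)[cnt == cnt[1]]
    if (length(winners) == 1) {
      if (winners != "-") out <- c(out, winners)
    } else if (sum(winners != "-") >= 2) {
      dropped <- dropped + 1L
    }
  }
  list(consensus_seq = paste(out, collapse = ""), n_dropped_columns = dropped)
}

# Random MSA-shaped rows (each with at least one base).
random_msa <- function(n_rows = sample(2:6, 1), width = sample(3:12, 1)) {
  repeat {
    rows <- vapply(seq_len(n_rows), function(i) {
      paste(sample(c("A", "C", "G", "T", "-"), width, replace = TRUE,
                   prob = c(0.2, 0.2, 0.2, 0.2, 0.2)), collapse = "")
    }, character(1))
    if (all(grepl("[ACGT]", rows))) return(rows)
  }
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Write a small FASTA from named sequences.
write_mini_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  writeLines(as.character(rbind(paste0(">", names(seqs)), unname(seqs))), path)
  path
}

# Write a SAM file from a header spec and raw alignment rows.
# refs: named integer vector of scaffold lengths.
# rows: list of lists with qname, flag, rname, pos (1-based), cigar, seq.
write_mini_sam <- function(refs, rows, path = tempfile(fileext = ".sam")) {
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(refs), refs))
  body <- vapply(rows, function(r) {
    paste(r$qname, r$flag, r$rname, r$pos, 60, r$cigar, "*", 0, 0,
          r$seq %||% "*",
          if (is.null(r$seq) || identical(r$seq, "*")) "*" else strrep("I", nchar(r$seq)),
          sep = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Write a small single-sample VCF. records: data.frame with chrom, pos
# (1-based), ref, alt, gt, and optional qual / dp columns.
write_mini_vcf <- function(records, sample = "s1", contigs = NULL,
                           path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    if (!is.null(contigs)) sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t")
  )
  has_dp <- "dp" %in% names(records)
  body <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    qual <- if ("qual" %in% names(records)) r$qual else 50
    fmt <- if (has_dp) "GT:DP" else "GT"
    val <- if (has_dp) paste0(r$gt, ":", r$dp) else r$gt
    paste(r$chrom, r$pos, ".", r$ref, r$alt, qual, "PASS", ".", fmt, val, sep = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}
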