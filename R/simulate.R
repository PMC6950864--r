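#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-fixture generator. The
#' defaults reproduce the study conditions the toolkit is built around:
#' gaps of the six fixed assembler sizes, long reads with a 6528 bp mean
#' length, and a diploid-like background heterozygosity with embedded ROH
#' tracts.
#'
#' @param seed master seed; each stage derives its own sub-seed so stages
#'   are individually reproducible.
#' @param genome_bp total truth-genome size in bp.
#' @param n_scaffolds number of scaffolds (genome split evenly).
#' @param gc GC fraction in (0,1).
#' @param gap_sizes integer vector of gap sizes to plant (repeats allowed),
#'   drawn from the fixed assembler sizes `{10,100,400,3000,5000,10000}`.
#' @param read_mean_len mean read length in bp (default 6528).
#' @param read_len_sd_log log-scale standard deviation of the log-normal
#'   read-length distribution (default 0.5).
#' @param depth target genome coverage of the read set.
#' @param err_sub,err_ins,err_del per-base substitution / insertion /
#'   deletion rates, each in `[0,1)`.
#' @param het_rate_bg background heterozygous-site rate per bp.
#' @param roh_tracts tibble with `scaffold`, `start`, `end`: intervals with
#'   zero heterozygosity.
#' @param flank flank width used when spacing gaps from scaffold ends.
#' @param min_split_gap gaps at least this long are emitted as split
#'   alignments (two records) by the read simulator.
#' @param min_gap_dist minimum distance between planted gaps (default 1000).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1, genome_bp = 2e6, n_scaffolds = 4, gc = 0.42,
                       gap_sizes = rep(c(10, 100, 400, 3000, 5000, 10000), each = 10),
                       read_mean_len = 6528, read_len_sd_log = 0.5, depth = 5,
                       err_sub = 0, err_ins = 0, err_del = 0,
                       het_rate_bg = 1e-3,
                       roh_tracts = tibble(scaffold = character(),
                                           start = double(), end = double()),
                       flank = 50, min_split_gap = 3000, min_gap_dist = 1000) {
  rates <- c(err_sub = err_sub, err_ins = err_ins, err_del = err_del,
             het_rate_bg = het_rate_bg)
  if (any(rates < 0 | rates >= 1)) abort_validation("rates must lie in [0, 1)")
  if (depth <= 0) abort_validation("depth must be positive")
  if (gc <= 0 || gc >= 1) abort_validation("gc must lie in (0, 1)")
  if (read_mean_len < 100) abort_validation("read_mean_len must be >= 100")
  gap_sizes <- as.integer(gap_sizes)
  if (length(gap_sizes) > 0) {
    need <- sum(gap_sizes + min_gap_dist) + n_scaffolds * 4 * flank
    if (need > genome_bp) {
      abort_validation(sprintf(
        "genome_bp = %d too small for %d gaps with %d bp spacing",
        genome_bp, length(gap_sizes), min_gap_dist
      ))
    }
  }
  check_columns(roh_tracts, c("scaffold", "start", "end"), "roh_tracts")
  structure(
    list(
      seed = seed, genome_bp = genome_bp, n_scaffolds = n_scaffolds, gc = gc,
      gap_sizes = gap_sizes, read_mean_len = read_mean_len,
      read_len_sd_log = read_len_sd_log, depth = depth,
      err_sub = err_sub, err_ins = err_ins, err_del = err_del,
      het_rate_bg = het_rate_bg, roh_tracts = roh_tracts, flank = flank,
      min_split_gap = min_split_gap, min_gap_dist = min_gap_dist
    ),
    class = "sim_config"
  )
}

#' Simulate a truth genome
#'
#' I.i.d. bases with `P(G) + P(C) = gc`, split into `n_scaffolds` scaffolds
#' of near-equal size. Deterministic for a fixed seed.
#'
#' @param cfg a [sim_config()].
#' @return assembly tibble (`scaffold`, `seq`, `length`).
#' @export
sim_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, 0))
  base_len <- floor(cfg$genome_bp / cfg$n_scaffolds)
  lens <- rep(base_len, cfg$n_scaffolds)
  lens[cfg$n_scaffolds] <- cfg$genome_bp - base_len * (cfg$n_scaffolds - 1)
  p <- c((1 - cfg$gc) / 2, cfg$gc / 2, cfg$gc / 2, (1 - cfg$gc) / 2)
  tibble(
    scaffold = sprintf("scaf%02d", seq_len(cfg$n_scaffolds)),
    seq = vapply(lens, function(n) {
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p), collapse = "")
    }, character(1)),
    length = as.integer(lens)
  )
}

#' Plant fixed-size gaps into a truth genome
#'
#' Each planted gap replaces a truth segment of exactly the nominal size
#' with that many `N`s, so the gapped assembly has the same length as the
#' truth. Gaps are kept at least `2 * flank` bp from scaffold ends and
#' `min_gap_dist` bp apart.
#'
#' @param truth truth assembly tibble from [sim_genome()].
#' @param cfg a [sim_config()].
#' @return list with `assembly` (gapped tibble) and `gap_truth` (tibble:
#'   `gap_id`, `scaffold`, `start`, `end`, `length`, `truth_seq`), the truth
#'   table sorted like [find_gaps()] output.
#' @export
sim_gapped_assembly <- function(truth, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, 1))
  if (length(cfg$gap_sizes) == 0) {
    return(list(
      assembly = truth,
      gap_truth = tibble(
        gap_id = character(), scaffold = character(), start = integer(),
        end = integer(), length = integer(), truth_seq = character()
      )
    ))
  }
  sizes <- sort(cfg$gap_sizes, decreasing = TRUE)   # place big gaps first
  placed <- vector("list", length(sizes))
  intervals <- setNames(vector("list", nrow(truth)), truth$scaffold)
  margin <- 2 * cfg$flank
  for (i in seq_along(sizes)) {
    size <- sizes[i]
    ok <- FALSE
    for (try in seq_len(2000)) {
      sc_i <- sample.int(nrow(truth), 1, prob = truth$length)
      sc <- truth$scaffold[sc_i]
      hi <- truth$length[sc_i] - size - margin
      if (hi <= margin) next
      start <- sample(margin:hi, 1)
      end <- start + size
      prev <- intervals[[sc]]
      clash <- !is.null(prev) && any(
        start < prev$end + cfg$min_gap_dist & end > prev$start - cfg$min_gap_dist
      )
      if (!clash) {
        intervals[[sc]] <- bind_rows(prev, tibble(start = start, end = end))
        placed[[i]] <- tibble(scaffold = sc, start = start, end = end, length = size)
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      abort_validation(sprintf("could not place a %d bp gap after 2000 tries", size))
    }
  }
  gap_truth <- list_rbind(placed) |>
    arrange(match(.data$scaffold, truth$scaffold), .data$start) |>
    group_by(.data$scaffold) |>
    mutate(gap_id = sprintf("%s_gap%03d", .data$scaffold, row_number())) |>
    ungroup()
  seqs <- setNames(truth$seq, truth$scaffold)
  gap_truth$truth_seq <- unname(substr(
    seqs[gap_truth$scaffold], gap_truth$start + 1L, gap_truth$end
  ))
  gapped <- truth
  for (i in seq_len(nrow(gap_truth))) {
    g <- gap_truth[i, ]
    s <- gapped$seq[gapped$scaffold == g$scaffold]
    substr(s, g$start + 1L, g$end) <- strrep("N", g$length)
    gapped$seq[gapped$scaffold == g$scaffold] <- s
  }
  list(
    assembly = gapped,
    gap_truth = select(gap_truth, "gap_id", "scaffold", "start", "end",
                       "length", "truth_seq")
  )
}

# Apply per-base errors to a truth segment, returning the read sequence and
# the interleaved op/refpos vectors (ops in reference order; insertions
# attach after the truth base they follow).
apply_read_errors <- function(segment_chars, ref_start, err_sub, err_ins, err_del) {
  L0 <- length(segment_chars)
  bases <- c("A", "C", "G", "T")
  del <- runif(L0) < err_del
  emitted <- segment_chars
  sub <- runif(L0) < err_sub & !del
  if (any(sub)) {
    # substitute with a uniformly random different base
    cur <- emitted[sub]
    alt <- sample(bases, sum(sub), replace = TRUE)
    same <- alt == cur
    while (any(same)) {
      alt[same] <- sample(bases, sum(same), replace = TRUE)
      same <- alt == cur
    }
    emitted[sub] <- alt
  }
  ins <- runif(L0) < err_ins
  n_ins <- sum(ins)
  key <- c(2 * seq_len(L0), 2 * which(ins) + 1L)
  op <- c(ifelse(del, "D", "M"), rep("I", n_ins))
  refp <- c(ref_start + seq_len(L0) - 1L, ref_start + which(ins) - 1L)
  chr <- c(ifelse(del, "", emitted), sample(bases, n_ins, replace = TRUE))
  o <- order(key)
  list(op = op[o], refp = refp[o], chr = chr[o])
}

# Compress an op vector into a CIGAR string, with optional soft clips.
ops_to_cigar <- function(ops, lead_clip = 0, trail_clip = 0) {
  r <- rle(ops)
  parts <- paste0(r$lengths, r$values)
  paste0(
    if (lead_clip > 0) paste0(lead_clip, "S") else "",
    paste(parts, collapse = ""),
    if (trail_clip > 0) paste0(trail_clip, "S") else ""
  )
}

#' Simulate noisy long reads with truth alignments
#'
#' Read lengths are log-normal with the configured mean; start positions are
#' uniform over the truth genome; substitution/insertion/deletion errors are
#' applied per base; about half the reads are reverse-complemented. The
#' truth SAM (against the gapped assembly) encodes where each read's bases
#' came from: reads crossing a gap shorter than `min_split_gap` are single
#' records whose CIGAR runs through the N run as `M`; reads crossing a larger
#' gap are split into primary + supplementary records whose soft clips carry
#' the unaligned middle. Reads falling entirely inside a large gap's truth
#' segment get no alignment record.
#'
#' @param truth truth assembly tibble.
#' @param gap_truth gap-truth tibble from [sim_gapped_assembly()].
#' @param cfg a [sim_config()].
#' @return list with `reads` (tibble: `read_id`, `seq` in original read
#'   orientation, `strand`, `scaffold`, `truth_start`, `truth_end`) and
#'   `sam` (character vector of SAM lines, coordinate-sorted, with header).
#' @export
sim_reads <- function(truth, gap_truth, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, 2))
  n_reads <- max(1L, round(cfg$depth * cfg$genome_bp / cfg$read_mean_len))
  meanlog <- log(cfg$read_mean_len) - cfg$read_len_sd_log^2 / 2
  lens <- pmax(100L, round(rlnorm(n_reads, meanlog, cfg$read_len_sd_log)))
  sc_idx <- sample.int(nrow(truth), n_reads, replace = TRUE, prob = truth$length)
  starts <- floor(runif(n_reads) * (truth$length[sc_idx] - 1))
  strands <- sample(c("+", "-"), n_reads, replace = TRUE)
  truth_chars <- lapply(truth$seq, function(s) strsplit(s, "")[[1]])
  big_gaps <- filter(gap_truth, .data$length >= cfg$min_split_gap)

  reads <- vector("list", n_reads)
  sam_body <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    sc <- truth$scaffold[sc_idx[i]]
    s0 <- starts[i]
    e0 <- min(s0 + lens[i], truth$length[sc_idx[i]])
    seg <- truth_chars[[sc_idx[i]]][(s0 + 1):e0]
    ev <- apply_read_errors(seg, s0, cfg$err_sub, cfg$err_ins, cfg$err_del)
    read_seq_fwd <- paste(ev$chr, collapse = "")
    read_id <- sprintf("read%06d", i)
    reads[[i]] <- tibble(
      read_id = read_id,
      seq = if (strands[i] == "-") reverse_complement(read_seq_fwd) else read_seq_fwd,
      strand = strands[i], scaffold = sc,
      truth_start = as.integer(s0), truth_end = as.integer(e0)
    )
    # segment the ops at large-gap boundaries
    bg <- big_gaps[big_gaps$scaffold == sc &
                     big_gaps$end > s0 & big_gaps$start < e0, ]
    consumes_read <- ev$op != "D"
    qoff_end <- cumsum(consumes_read)           # read offset after each op
    read_len_total <- qoff_end[length(qoff_end)]
    if (nrow(bg) == 0) {
      region <- rep(0L, length(ev$op))
    } else {
      breaks <- sort(c(bg$start, bg$end))
      region <- findInterval(ev$refp, breaks)   # odd regions = inside a gap
    }
    flag_base <- if (strands[i] == "-") 16L else 0L
    recs <- character(0)
    first <- TRUE
    for (reg in sort(unique(region[region %% 2 == 0]))) {
      in_reg <- region == reg
      if (!any(ev$op[in_reg] == "M")) next
      idx <- which(in_reg)
      # CIGAR cannot start or end with D/I relative to the record: trim to M
      m_idx <- idx[ev$op[idx] == "M"]
      idx <- idx[idx >= m_idx[1] & idx <= m_idx[length(m_idx)]]
      lead <- if (idx[1] == 1L) 0L else qoff_end[idx[1] - 1L]
      trail <- read_len_total - qoff_end[idx[length(idx)]]
      cig <- ops_to_cigar(ev$op[idx], lead, trail)
      flag <- flag_base + if (first) 0L else 2048L
      recs <- c(recs, paste(
        read_id, flag, sc, ev$refp[idx[1]] + 1L, 60L, cig, "*", 0L, 0L,
        read_seq_fwd, strrep("I", nchar(read_seq_fwd)),
        sep = "\t"
      ))
      first <- FALSE
    }
    sam_body[[i]] <- recs
  }
  reads <- list_rbind(reads)
  body <- unlist(sam_body)
  # coordinate-sort the body
  f <- strsplit(body, "\t", fixed = TRUE)
  ord <- order(
    match(vapply(f, `[[`, character(1), 3), truth$scaffold),
    as.integer(vapply(f, `[[`, character(1), 4))
  )
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", truth$scaffold, truth$length),
    sprintf("@CO\tspanfill simulator seed=%s", format(cfg$seed))
  )
  list(reads = reads, sam = c(header, body[ord]))
}

#' Simulate a VCF with planted heterozygosity and ROH tracts
#'
#' Heterozygous sites (`GT 0/1`) follow a Poisson process at
#' `het_rate_bg` per bp outside the configured ROH tracts and are absent
#' inside them. Homozygous-alt sites (`GT 1/1`) at half the background rate
#' are scattered everywhere, so genotype filtering is exercised. Deterministic
#' per seed.
#'
#' @param scaffold_lengths tibble with `scaffold`, `length`.
#' @param cfg a [sim_config()].
#' @param sample_name sample column name (default `"sim"`).
#' @return list with `sites` (tibble: `scaffold`, `pos` 0-based, `gt`) and
#'   `vcf` (character vector of VCF lines).
#' @export
sim_vcf <- function(scaffold_lengths, cfg, sample_name = "sim") {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, 3))
  tr <- cfg$roh_tracts
  if (nrow(tr) > 1) {
    by_sc <- split(tr, tr$scaffold)
    for (t in by_sc) {
      t <- arrange(t, .data$start)
      if (nrow(t) > 1 && any(t$start[-1] < t$end[-nrow(t)])) {
        abort_validation("overlapping ROH tracts")
      }
    }
  }
  bad_tr <- left_join(tr, scaffold_lengths, by = "scaffold")
  if (anyNA(bad_tr$length) || any(bad_tr$end > bad_tr$length) || any(bad_tr$start < 0)) {
    abort_validation("ROH tract outside scaffold bounds")
  }
  sites <- purrr::pmap(scaffold_lengths[c("scaffold", "length")], function(scaffold, length) {
    n_het <- rpois(1, cfg$het_rate_bg * length)
    het_pos <- sort(sample.int(length, min(n_het, length))) - 1L
    t <- tr[tr$scaffold == scaffold, ]
    if (nrow(t) > 0) {
      inside <- rep(FALSE, length(het_pos))
      for (k in seq_len(nrow(t))) {
        inside <- inside | (het_pos >= t$start[k] & het_pos < t$end[k])
      }
      het_pos <- het_pos[!inside]
    }
    n_hom <- rpois(1, cfg$het_rate_bg / 2 * length)
    hom_pos <- sort(sample.int(length, min(n_hom, length))) - 1L
    hom_pos <- setdiff(hom_pos, het_pos)
    tibble(
      scaffold = scaffold,
      pos = c(het_pos, hom_pos),
      gt = c(rep("0/1", length(het_pos)), rep("1/1", length(hom_pos)))
    ) |> arrange(.data$pos)
  }) |> list_rbind()
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nrow(sites), replace = TRUE)
  alt <- sample(bases, nrow(sites), replace = TRUE)
  same <- alt == ref
  while (any(same)) {
    alt[same] <- sample(bases, sum(same), replace = TRUE)
    same <- alt == ref
  }
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##spanfill_sim_seed=%s", format(cfg$seed)),
    sprintf("##contig=<ID=%s,length=%d>", scaffold_lengths$scaffold, scaffold_lengths$length),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  )
  body <- if (nrow(sites) == 0) character(0) else paste(
    sites$scaffold, sites$pos + 1L, ".", ref, alt, 50, "PASS", ".", "GT", sites$gt,
    sep = "\t"
  )
  list(sites = sites, vcf = c(header, body))
}

#' Write a complete synthetic fixture to a directory
#'
#' Runs all simulator stages and writes: `truth.fa`, `gapped.fa`, `gaps.tsv`
#' (gap truth table), `reads.fastq`, `reads.sam`, `sites.vcf`, and
#' `manifest.json` (config snapshot, seed, file checksums, timestamp).
#' Outputs other than the manifest are byte-identical across runs with the
#' same config.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @return (invisibly) list with the in-memory stage outputs (`truth`,
#'   `gapped`, `gap_truth`, `reads`, `sam`, `sites`) and `paths`.
#' @export
sim_fixture <- function(cfg, dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- sim_genome(cfg)
  gp <- sim_gapped_assembly(truth, cfg)
  rd <- sim_reads(truth, gp$gap_truth, cfg)
  vc <- sim_vcf(select(truth, "scaffold", "length"), cfg)
  paths <- list(
    truth = file.path(dir, "truth.fa"),
    gapped = file.path(dir, "gapped.fa"),
    gaps = file.path(dir, "gaps.tsv"),
    fastq = file.path(dir, "reads.fastq"),
    sam = file.path(dir, "reads.sam"),
    vcf = file.path(dir, "sites.vcf"),
    manifest = file.path(dir, "manifest.json")
  )
  write_assembly(truth, paths$truth)
  write_assembly(gp$assembly, paths$gapped)
  writeLines(c(
    sprintf("# spanfill simulator seed=%s", format(cfg$seed)),
    paste(names(gp$gap_truth), collapse = "\t"),
    do.call(paste, c(gp$gap_truth, sep = "\t"))
  ), paths$gaps)
  writeLines(as.character(rbind(
    paste0("@", rd$reads$read_id),
    rd$reads$seq,
    "+",
    strrep("I", nchar(rd$reads$seq))
  )), paths$fastq)
  writeLines(rd$sam, paths$sam)
  writeLines(vc$vcf, paths$vcf)
  manifest <- list(
    tool = "spanfill", version = as.character(utils::packageVersion("spanfill")),
    command = "sim_fixture", seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "roh_tracts")],
    roh_tracts = as.data.frame(cfg$roh_tracts),
    checksums = as.list(tools::md5sum(unlist(paths[names(paths) != "manifest"]))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(
    truth = truth, gapped = gp$assembly, gap_truth = gp$gap_truth,
    reads = rd$reads, sam = rd$sam, sites = vc$sites, paths = paths
  ))
}
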