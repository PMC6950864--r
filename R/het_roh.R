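#' Read heterozygous site positions from a VCF
#'
#' A site is heterozygous when the named sample's genotype has two called,
#' distinct alleles (phased or unphased); missing and homozygous genotypes
#' are excluded, multi-allelic heterozygotes (e.g. `1/2`) are included, and
#' indel records are excluded by default. Optional site filters mirror the
#' usual depth/quality thresholds applied before ROH analysis.
#'
#' @param vcf_path path to a VCF file (plain or bgzipped).
#' @param sample sample name carrying the genotypes.
#' @param min_dp optional minimum per-sample `DP`; records without a `DP`
#'   field pass when the filter is unset.
#' @param min_qual optional minimum site `QUAL`.
#' @param include_indels keep records whose REF or called ALT allele is not a
#'   single base (default `FALSE`).
#' @return tibble with columns `scaffold` and `pos` (0-based site positions),
#'   sorted within scaffold.
#' @export
read_het_sites <- function(vcf_path, sample, min_dp = NULL, min_qual = NULL,
                           include_indels = FALSE) {
  if (!file.exists(vcf_path)) abort_io(sprintf("VCF file not found: %s", vcf_path))
  vcf <- tryCatch(
    vcfR::read.vcfR(vcf_path, verbose = FALSE),
    error = function(e) abort_io(sprintf("failed to parse VCF '%s': %s", vcf_path, conditionMessage(e)))
  )
  if (nrow(vcf@fix) == 0) {
    return(tibble(scaffold = character(), pos = integer()))
  }
  samples <- colnames(vcf@gt)[-1]
  if (!sample %in% samples) {
    abort_validation(sprintf(
      "sample '%s' not in VCF (has: %s)", sample, paste(samples, collapse = ", ")
    ))
  }
  fix <- vcf@fix
  gt <- vcfR::extract.gt(vcf, element = "GT")[, sample]
  keep <- rep(TRUE, length(gt))
  if (!is.null(min_qual)) {
    qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
    keep <- keep & !is.na(qual) & qual >= min_qual
  }
  if (!is.null(min_dp)) {
    dp <- suppressWarnings(as.numeric(vcfR::extract.gt(vcf, element = "DP")[, sample]))
    keep <- keep & !is.na(dp) & dp >= min_dp
  }
  alleles <- strsplit(ifelse(is.na(gt), ".", gt), "[/|]")
  n_bad <- sum(lengths(alleles) != 2 & !vapply(alleles, function(a) identical(a, "."), logical(1)))
  if (n_bad > 0) warn(sprintf("%d record(s) with malformed GT skipped", n_bad))
  is_het <- vapply(alleles, function(a) {
    length(a) == 2 && !any(a == ".") && !anyNA(suppressWarnings(as.integer(a))) &&
      a[1] != a[2]
  }, logical(1))
  if (!include_indels) {
    alt_list <- strsplit(ifelse(is.na(fix[, "ALT"]), "", fix[, "ALT"]), ",")
    is_indel <- nchar(fix[, "REF"]) != 1 |
      vapply(alt_list, function(a) any(nchar(a) != 1), logical(1))
    keep <- keep & !is_indel
  }
  sel <- which(keep & is_het)
  tibble(
    scaffold = fix[sel, "CHROM"],
    pos = as.integer(fix[sel, "POS"]) - 1L
  ) |>
    arrange(.data$scaffold, .data$pos)
}

#' Count heterozygous sites in fixed-width windows
#'
#' Tiles each scaffold with `bin_size` windows (the last window is truncated
#' to the scaffold end and normalised by its true width) and counts the het
#' sites falling in each.
#'
#' @param het_sites tibble with `scaffold`, `pos` (see [read_het_sites()]).
#' @param scaffold_lengths tibble with `scaffold`, `length`.
#' @param bin_size window width in bp (default 1e6).
#' @return tibble with `scaffold`, `bin_start`, `bin_end`, `het_count`,
#'   `het_per_kb`.
#' @export
het_windows <- function(het_sites, scaffold_lengths, bin_size = 1e6) {
  check_columns(het_sites, c("scaffold", "pos"), "het_sites")
  check_columns(scaffold_lengths, c("scaffold", "length"), "scaffold_lengths")
  bad <- left_join(het_sites, scaffold_lengths, by = "scaffold")
  if (anyNA(bad$length)) {
    abort_validation("het site on a scaffold absent from scaffold_lengths")
  }
  if (any(bad$pos >= bad$length)) {
    abort_validation("het site position beyond scaffold length")
  }
  wins <- purrr::pmap(scaffold_lengths[c("scaffold", "length")], function(scaffold, length) {
    starts <- seq(0, length - 1, by = bin_size)
    tibble(
      scaffold = scaffold, bin_start = as.integer(starts),
      bin_end = as.integer(pmin(starts + bin_size, length))
    )
  }) |> list_rbind()
  counts <- het_sites |>
    mutate(bin_start = as.integer(floor(.data$pos / bin_size) * bin_size)) |>
    count(.data$scaffold, .data$bin_start, name = "het_count")
  wins |>
    left_join(counts, by = c("scaffold", "bin_start")) |>
    mutate(
      het_count = ifelse(is.na(.data$het_count), 0L, .data$het_count),
      het_per_kb = .data$het_count / ((.data$bin_end - .data$bin_start) / 1000)
    )
}

#' Histogram of windows by heterozygosity density
#'
#' @param windows tibble from [het_windows()].
#' @param breaks lower bin edges for `het_per_kb` (default `seq(0, 2, 0.2)`);
#'   the last interval is open-ended.
#' @return tibble with `het_per_kb_lo`, `het_per_kb_hi`, `n_bins`.
#' @export
het_histogram <- function(windows, breaks = seq(0, 2, by = 0.2)) {
  check_columns(windows, "het_per_kb", "windows")
  edges <- c(breaks, Inf)
  idx <- findInterval(windows$het_per_kb, edges, rightmost.closed = FALSE)
  tibble(
    het_per_kb_lo = edges[seq_along(breaks)],
    het_per_kb_hi = edges[seq_along(breaks) + 1],
    n_bins = tabulate(idx, nbins = length(breaks))
  )
}

# ROH length classes, half-open boundaries:
# sub < 10 kb <= short < 100 kb <= medium < 1 Mb <= long.
roh_length_class <- function(length) {
  dplyr::case_when(
    length >= 1e6 ~ "long",
    length >= 1e5 ~ "medium",
    length >= 1e4 ~ "short",
    TRUE ~ "sub"
  )
}

#' Read ROH segments from a BCFtools RoH table
#'
#' Parses the `RG` lines of BCFtools RoH output
#' (`RG <sample> <chrom> <start> <end> <length> ...`, 1-based inclusive
#' coordinates), converts to 0-based half-open, recomputes lengths from the
#' coordinates (warning when the file's length column disagrees), and warns
#' on overlapping segments within a scaffold. Non-RG lines are ignored.
#'
#' @param path path to the table.
#' @param sample optional: keep only this sample's segments.
#' @return tibble with `scaffold`, `start`, `end`, `length`, `length_class`,
#'   sorted within scaffold.
#' @export
read_roh_segments <- function(path, sample = NULL) {
  if (!file.exists(path)) abort_io(sprintf("ROH table not found: %s", path))
  lines <- readr::read_lines(path)
  rg <- lines[startsWith(lines, "RG")]
  if (length(rg) == 0) {
    return(tibble(
      scaffold = character(), start = integer(), end = integer(),
      length = integer(), length_class = character()
    ))
  }
  parts <- strsplit(rg, "\t", fixed = TRUE)
  if (any(lengths(parts) < 6)) {
    abort_validation("unparsable RG line (need at least 6 tab-separated fields)")
  }
  start1 <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 4)))
  end1 <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 5)))
  file_len <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 6)))
  if (anyNA(start1) || anyNA(end1)) abort_validation("unparsable RG line coordinates")
  seg <- tibble(
    sample = vapply(parts, `[[`, character(1), 2),
    scaffold = vapply(parts, `[[`, character(1), 3),
    start = start1 - 1L,                      # to 0-based half-open
    end = end1
  )
  if (!is.null(sample)) seg <- seg[seg$sample == sample, , drop = FALSE]
  seg <- seg |>
    mutate(length = .data$end - .data$start, length_class = roh_length_class(.data$length)) |>
    select(-"sample") |>
    arrange(.data$scaffold, .data$start)
  mism <- sum(abs(file_len - (end1 - start1 + 1L)) > 1, na.rm = TRUE)
  if (mism > 0) {
    warn(sprintf("%d RG line(s) whose length column disagrees with the coordinates", mism))
  }
  ovl <- seg |>
    group_by(.data$scaffold) |>
    summarise(any_ovl = any(.data$start[-1] < .data$end[-n()]), .groups = "drop")
  if (any(ovl$any_ovl, na.rm = TRUE)) {
    warn("overlapping ROH segments within a scaffold; all kept")
  }
  seg
}

#' Summarise ROH segments by length class
#'
#' @param segments tibble with `length` and optionally `length_class`
#'   (recomputed when absent).
#' @param genome_size genome size in bp used for the fractions.
#' @return tibble with one row per class (`short`, `medium`, `long`, and
#'   `sub` reported separately): `length_class`, `n`, `bp`, `fraction`.
#' @export
roh_summary <- function(segments, genome_size) {
  if (genome_size <= 0) abort_validation("genome_size must be positive")
  classes <- c("short", "medium", "long", "sub")
  if (nrow(segments) == 0) {
    return(tibble(length_class = classes, n = 0L, bp = 0, fraction = 0))
  }
  if (!"length_class" %in% names(segments)) {
    segments$length_class <- roh_length_class(segments$length)
  }
  got <- segments |>
    group_by(.data$length_class) |>
    summarise(n = n(), bp = sum(.data$length), .groups = "drop")
  tibble(length_class = classes) |>
    left_join(got, by = "length_class") |>
    mutate(
      n = ifelse(is.na(.data$n), 0L, .data$n),
      bp = ifelse(is.na(.data$bp), 0, .data$bp),
      fraction = .data$bp / genome_size
    )
}

#' Call ROH-like segments from low-heterozygosity windows
#'
#' Merges maximal runs of consecutive windows whose `het_per_kb` does not
#' exceed the threshold into single segments - the windowed proxy for runs
#' of homozygosity. Window-resolution only: tracts shorter than a window are
#' invisible, and boundaries are accurate to one window.
#'
#' @param windows tibble from [het_windows()].
#' @param max_het_per_kb threshold below which a window counts as
#'   homozygous (default 0.1 het sites per kb).
#' @return tibble with `scaffold`, `start`, `end`, `length`, `length_class`.
#' @export
proxy_roh_from_windows <- function(windows, max_het_per_kb = 0.1) {
  check_columns(windows, c("scaffold", "bin_start", "bin_end", "het_per_kb"), "windows")
  low_bins <- windows |>
    arrange(.data$scaffold, .data$bin_start) |>
    group_by(.data$scaffold) |>
    mutate(
      low = .data$het_per_kb <= max_het_per_kb,
      run = cumsum(.data$low != dplyr::lag(.data$low, default = FALSE) & .data$low)
    ) |>
    ungroup() |>
    filter(.data$low)
  if (nrow(low_bins) == 0) {
    return(tibble(
      scaffold = character(), start = integer(), end = integer(),
      length = integer(), length_class = character()
    ))
  }
  runs <- low_bins |>
    group_by(.data$scaffold, .data$run) |>
    summarise(start = min(.data$bin_start), end = max(.data$bin_end), .groups = "drop")
  runs |>
    mutate(length = .data$end - .data$start, length_class = roh_length_class(.data$length)) |>
    select("scaffold", "start", "end", "length", "length_class") |>
    arrange(.data$scaffold, .data$start)
}
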