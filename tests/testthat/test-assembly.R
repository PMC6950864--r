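test_that("read_assembly normalizes case, wrapping and ambiguity codes", {
  p <- tempfile(fileext = ".fa")
  writeLines(c(">s1", "ACGT"), p)
  asm <- read_assembly(p)
  expect_equal(asm$scaffold, "s1")
  expect_equal(asm$seq, "ACGT")
  expect_equal(asm$length, 4L)

  writeLines(c(">s1", "acg", "t"), p)
  expect_equal(read_assembly(p)$seq, "ACGT")

  writeLines(c(">s1", "ACRT"), p)
  expect_warning(asm <- read_assembly(p), "coerced to N")
  expect_equal(asm$seq, "ACNT")
})

test_that("read_assembly rejects broken input", {
  expect_error(read_assembly(tempfile()), class = "spanfill_io_error")
  p <- tempfile(fileext = ".fa")
  writeLines(c(">s1", "ACGT", ">s1", "GGGG"), p)
  expect_error(read_assembly(p), class = "spanfill_validation_error")
  writeLines(c(">s1", "", ">s2", "ACGT"), p)
  expect_error(read_assembly(p), class = "spanfill_validation_error")
})

test_that("find_gaps reports maximal N-runs above the length cutoff", {
  asm <- tibble::tibble(
    scaffold = "s",
    seq = paste0(strrep("A", 60), strrep("N", 10), strrep("C", 60))
  )
  g <- find_gaps(asm)
  expect_equal(g$start, 60L)
  expect_equal(g$end, 70L)
  expect_equal(g$length, 10L)
  expect_equal(g$gap_id, "s_gap001")

  expect_equal(nrow(find_gaps(tibble::tibble(scaffold = "s", seq = "ACGT"))), 0L)

  # a 9-run is ignored at the default cutoff, the 10-run is kept
  asm2 <- tibble::tibble(
    scaffold = "s",
    seq = paste0(strrep("A", 5), strrep("N", 9), strrep("A", 5),
                 strrep("N", 10), strrep("A", 5))
  )
  g2 <- find_gaps(asm2, min_gap_length = 10)
  expect_equal(nrow(g2), 1L)
  expect_equal(g2$length, 10L)
})

test_that("gap segments and non-gap segments reconstruct the scaffold", {
  set.seed(11)
  for (rep in 1:5) {
    chunks <- c(random_seq(sample(20:80, 1)), strrep("N", sample(10:30, 1)),
                random_seq(sample(20:80, 1)), strrep("N", sample(10:30, 1)),
                random_seq(sample(20:80, 1)))
    asm <- tibble::tibble(scaffold = "s", seq = paste(chunks, collapse = ""))
    g <- find_gaps(asm)
    expect_true(all(g$start[-1] >= g$end[-nrow(g)]))          # no overlap
    # rebuild: alternate non-gap and gap substrings in coordinate order
    bounds <- sort(c(0L, g$start, g$end, nchar(asm$seq)))
    rebuilt <- paste(substring(asm$seq, head(bounds, -1) + 1, bounds[-1]), collapse = "")
    expect_identical(rebuilt, asm$seq)
    expect_true(all(substring(asm$seq, g$start + 1, g$end) ==
                      strrep("N", g$length)))
  }
})

test_that("calc_n50 matches the brute-force definition", {
  expect_equal(calc_n50(c(40, 30, 20, 10)), 30L)
  set.seed(21)
  for (i in 1:30) {
    lens <- sample(1:5000, sample(1:200, 1), replace = TRUE)
    expect_equal(calc_n50(lens), n50_oracle(lens))
  }
})

test_that("assembly_stats splits contigs at the N-run threshold", {
  one <- tibble::tibble(scaffold = "s", seq = "ACGT")
  st <- assembly_stats(one)
  expect_equal(st$n_contigs, 1L)
  expect_equal(st$contig_n50, 4L)
  expect_equal(st$scaffold_n50, 4L)
  expect_equal(st$total_N, 0L)

  asm <- tibble::tibble(
    scaffold = "s",
    seq = paste0(strrep("A", 100), strrep("N", 10), strrep("A", 50))
  )
  st <- assembly_stats(asm)
  expect_equal(st$n_contigs, 2L)
  expect_equal(st$total_N, 10L)
  expect_equal(st$scaffold_n50, 160L)
  expect_equal(st$contig_n50, 100L)
  expect_equal(st$mean_contig, 75L)
  expect_true(st$contig_n50 <= st$scaffold_n50)
  expect_error(assembly_stats(one[0, ]), class = "spanfill_validation_error")
})

test_that("contig lengths plus broken-run Ns account for every base", {
  set.seed(31)
  for (rep in 1:5) {
    # random mix of sequence, short N runs (< 10) and long N runs (>= 10)
    parts <- unlist(lapply(1:8, function(i) {
      c(random_seq(sample(10:50, 1)), strrep("N", sample(c(2:8, 10:25), 1)))
    }))
    seq <- paste(c(parts, random_seq(20)), collapse = "")
    asm <- tibble::tibble(scaffold = "s", seq = seq)
    st <- assembly_stats(asm, contig_break_n = 10)
    long_runs <- find_gaps(asm, min_gap_length = 10)
    contigs <- strsplit(seq, "N{10,}", perl = TRUE)[[1]]
    expect_equal(sum(nchar(contigs)) + sum(long_runs$length), st$total_bp)
  }
})

test_that("write_assembly wraps lines and round-trips exactly", {
  asm <- tibble::tibble(scaffold = "s", seq = random_seq(130))
  p <- tempfile(fileext = ".fa")
  write_assembly(asm, p, line_width = 60)
  lines <- readLines(p)
  expect_equal(nchar(lines[-1]), c(60L, 60L, 10L))

  set.seed(41)
  multi <- tibble::tibble(
    scaffold = sprintf("sc%02d", 1:10),
    seq = vapply(sample(50:300, 10), random_seq, character(1))
  )
  multi$length <- nchar(multi$seq)
  p2 <- tempfile(fileext = ".fa")
  write_assembly(multi, p2)
  back <- read_assembly(p2)
  expect_identical(back$scaffold, multi$scaffold)
  expect_identical(back$seq, multi$seq)

  expect_error(write_assembly(multi[0, ], p2), class = "spanfill_validation_error")
})

test_that("gap_flanks returns adjacent non-N sequence, truncated at N runs", {
  seq <- paste0(strrep("A", 20), strrep("N", 10), strrep("C", 20))
  fl <- gap_flanks(seq, 20, 30, flank = 50)
  expect_equal(fl$left, strrep("A", 20))
  expect_equal(fl$right, strrep("C", 20))
  # neighbouring N-run within flank range is trimmed away
  seq2 <- paste0("NN", strrep("A", 5), strrep("N", 10), strrep("C", 60))
  fl2 <- gap_flanks(seq2, 7, 17, flank = 50)
  expect_equal(fl2$left, strrep("A", 5))
  expect_equal(fl2$right, strrep("C", 50))
})
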