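gap_90_100 <- tibble::tibble(
  gap_id = "s_gap001", scaffold = "s", start = 90L, end = 100L, length = 10L
)

mk_unsplit_aln <- function(ref_start, ref_end, seq = NULL) {
  len <- ref_end - ref_start
  tibble::tibble(
    read_id = "r1", scaffold = "s", ref_start = ref_start, ref_end = ref_end,
    read_start = 0L, read_end = len, qstart_fwd = 0L, qend_fwd = len,
    read_len = len, strand = "+", cigar = paste0(len, "M"),
    seq_fwd = seq %||% random_seq(len), is_split_part = FALSE
  )
}

test_that("unsplit pathway requires the 50 bp anchor on both sides", {
  aln <- mk_unsplit_aln(0L, 200L)
  ev <- unsplit_spanning(aln, gap_90_100, flank = 50)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$pathway, "unsplit")
  expect_equal(nchar(ev$extracted_seq), 110L)
  expect_equal(ev$extracted_seq, substr(aln$seq_fwd, 41, 150))
  expect_equal(ev$left_anchor_bp, 90L)
  expect_equal(ev$right_anchor_bp, 100L)

  # left anchor one base short of 50 bp
  expect_equal(nrow(unsplit_spanning(mk_unsplit_aln(45L, 200L), gap_90_100)), 0L)
  # exactly at both thresholds qualifies
  ev2 <- unsplit_spanning(mk_unsplit_aln(40L, 150L), gap_90_100)
  expect_equal(nrow(ev2), 1L)
  expect_equal(ev2$left_anchor_bp, 50L)
  # split parts never feed the unsplit pathway
  spl <- mk_unsplit_aln(0L, 200L)
  spl$is_split_part <- TRUE
  expect_equal(nrow(unsplit_spanning(spl, gap_90_100)), 0L)
})

test_that("split pathway extracts the read interval between the mapped parts", {
  gap <- tibble::tibble(gap_id = "g", scaffold = "s", start = 10000L,
                        end = 15000L, length = 5000L)
  full <- random_seq(7000)
  parts <- tibble::tibble(
    read_id = "r1", scaffold = "s",
    ref_start = c(8000L, 15000L), ref_end = c(10000L, 16000L),
    read_start = c(0L, 6000L), read_end = c(2000L, 7000L),
    qstart_fwd = c(0L, 6000L), qend_fwd = c(2000L, 7000L),
    read_len = 7000L, strand = "+",
    cigar = c("2000M5000S", "6000S1000M"),
    seq_fwd = full, is_split_part = TRUE
  )
  ev <- split_spanning(parts, gap)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$pathway, "split")
  expect_equal(nchar(ev$extracted_seq), 4000L)
  expect_equal(ev$extracted_seq, substr(full, 2001, 6000))

  # below the 3 kb threshold the pathway is inert
  small <- tibble::tibble(gap_id = "g", scaffold = "s", start = 10000L,
                          end = 10400L, length = 400L)
  expect_equal(nrow(split_spanning(parts, small)), 0L)

  # opposite strands disqualify the group
  parts2 <- parts
  parts2$strand <- c("+", "-")
  expect_equal(nrow(split_spanning(parts2, gap)), 0L)

  # parts too far from the gap edge disqualify
  parts3 <- parts
  parts3$ref_end[1] <- 9800L
  expect_equal(nrow(split_spanning(parts3, gap, max_side_dist = 100)), 0L)
})

test_that("ambiguous >2-part split groups are skipped with a warning", {
  gap <- tibble::tibble(gap_id = "g", scaffold = "s", start = 10000L,
                        end = 15000L, length = 5000L)
  full <- random_seq(9000)
  parts <- tibble::tibble(
    read_id = "r1", scaffold = "s",
    ref_start = c(8000L, 15000L, 15050L),
    ref_end = c(10000L, 15040L, 16000L),
    read_start = c(0L, 6000L, 8000L), read_end = c(2000L, 6040L, 8950L),
    qstart_fwd = c(0L, 6000L, 8000L), qend_fwd = c(2000L, 6040L, 8950L),
    read_len = 9000L, strand = "+",
    cigar = c("2000M7000S", "6000S40M2960S", "8000S950M50S"),
    seq_fwd = full, is_split_part = TRUE
  )
  expect_warning(ev <- split_spanning(parts, gap), "ambiguous|skipped")
  expect_equal(nrow(ev), 0L)
})

test_that("evidence from simulator truth equals the truth genome segments", {
  cfg <- sim_config(seed = 101, genome_bp = 2e5, n_scaffolds = 1, depth = 8,
                    gap_sizes = c(10, 100, 400, 3000, 5000))
  truth <- sim_genome(cfg)
  gp <- sim_gapped_assembly(truth, cfg)
  rd <- sim_reads(truth, gp$gap_truth, cfg)
  sam <- tempfile(fileext = ".sam")
  writeLines(rd$sam, sam)
  aln <- read_alignments(sam)
  gaps <- find_gaps(gp$assembly)
  ev <- gap_evidence(aln, gaps)
  expect_gt(nrow(ev), 0)
  tseq <- truth$seq[1]
  by_gap <- split(ev, ev$gap_id)
  for (gid in names(by_gap)) {
    g <- gaps[gaps$gap_id == gid, ]
    for (i in seq_len(nrow(by_gap[[gid]]))) {
      e <- by_gap[[gid]][i, ]
      want <- if (e$pathway == "unsplit") {
        substr(tseq, g$start - 50 + 1, g$end + 50)
      } else {
        substr(tseq, g$start + 1, g$end)
      }
      expect_identical(e$extracted_seq, want)
    }
  }
  # no evidence from alignments that do not overlap the gap
  for (gid in names(by_gap)) {
    g <- gaps[gaps$gap_id == gid, ]
    for (rid in by_gap[[gid]]$read_id) {
      spans <- aln[aln$read_id == rid, ]
      expect_true(any(spans$ref_start < g$end + 100 & spans$ref_end > g$start - 100))
    }
  }
})

test_that("duplicate unsplit+split evidence keeps the unsplit record", {
  gap <- tibble::tibble(gap_id = "g", scaffold = "s", start = 10000L,
                        end = 13000L, length = 3000L)
  full <- random_seq(7000)
  spanner <- tibble::tibble(
    read_id = "r1", scaffold = "s", ref_start = 8000L, ref_end = 15000L,
    read_start = 0L, read_end = 7000L, qstart_fwd = 0L, qend_fwd = 7000L,
    read_len = 7000L, strand = "+", cigar = "7000M",
    seq_fwd = full, is_split_part = FALSE
  )
  splitp <- tibble::tibble(
    read_id = "r1", scaffold = "s",
    ref_start = c(8000L, 13000L), ref_end = c(10000L, 15000L),
    read_start = c(0L, 5000L), read_end = c(2000L, 7000L),
    qstart_fwd = c(0L, 5000L), qend_fwd = c(2000L, 7000L),
    read_len = 7000L, strand = "+",
    cigar = c("2000M5000S", "5000S2000M"),
    seq_fwd = full, is_split_part = TRUE
  )
  expect_warning(
    ev <- gap_evidence(dplyr::bind_rows(spanner, splitp), gap),
    "unsplit"
  )
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$pathway, "unsplit")
})
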