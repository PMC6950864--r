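mk_gap <- function(start = 60L, end = 70L) {
  tibble::tibble(gap_id = "s_gap001", scaffold = "s",
                 start = start, end = end, length = end - start)
}

mk_ev <- function(seqs, pathway = "unsplit") {
  tibble::tibble(
    gap_id = "s_gap001", read_id = sprintf("r%d", seq_along(seqs)),
    pathway = pathway, extracted_seq = seqs,
    left_anchor_bp = 60L, right_anchor_bp = 60L
  )
}

test_that("close_gap handles uncovered, fallback and consensus cases", {
  g <- mk_gap()
  L <- strrep("A", 50); R <- strrep("C", 50)

  un <- close_gap(g, mk_ev(character(0)), L, R)
  expect_equal(un$status, "uncovered")
  expect_equal(un$replacement_seq, "")
  expect_equal(un$coverage, 0L)
  expect_equal(c(un$replace_start, un$replace_end), c(10L, 120L))

  # single unsplit read: raw extracted sequence, flanks already read-derived
  mid <- random_seq(10)
  one <- close_gap(g, mk_ev(paste0(L, mid, R)), L, R)
  expect_true(one$used_fallback)
  expect_equal(one$status, "closed")
  expect_equal(one$replacement_seq, paste0(L, mid, R))

  # single split read: the unmapped middle gets wrapped in reference flanks
  one_sp <- close_gap(g, mk_ev(mid, pathway = "split"), L, R)
  expect_equal(one_sp$replacement_seq, paste0(L, mid, R))

  # three identical extracted sequences: consensus equals them
  three <- close_gap(g, mk_ev(rep(paste0(L, mid, R), 3)), L, R)
  expect_false(three$used_fallback)
  expect_equal(three$replacement_seq, paste0(L, mid, R))
  expect_equal(three$status, "closed")
})

test_that("irreconcilable evidence leaves the gap ambiguous", {
  g <- mk_gap()
  L <- strrep("A", 50); R <- strrep("C", 50)
  # two unrelated sequences tie at almost every column
  amb <- close_gap(g, mk_ev(c(strrep("G", 110), strrep("T", 110))), L, R)
  expect_equal(amb$status, "ambiguous")
  expect_equal(amb$replacement_seq, "")
})

test_that("patch_assembly splices replacements and reports sizes", {
  asm <- tibble::tibble(
    scaffold = "s",
    seq = paste0(strrep("A", 60), strrep("N", 10), strrep("C", 60)),
    length = 130L
  )
  gaps <- find_gaps(asm)

  # zero closed actions: identity
  acts0 <- close_gaps(asm, gaps, mk_ev(character(0))[0, ])
  cl0 <- patch_assembly(asm, acts0, gaps = gaps)
  expect_identical(cl0$assembly$seq, asm$seq)
  expect_equal(glance(cl0)$bp_change, 0L)

  # replacement of the flanked interval [10, 120) by a 105 bp sequence
  acts <- tibble::tibble(
    gap_id = "s_gap001", scaffold = "s", replace_start = 10L, replace_end = 120L,
    replacement_seq = random_seq(105), status = "closed", coverage = 3L,
    pathway = "unsplit", used_fallback = FALSE, n_dropped_columns = 0L
  )
  cl <- patch_assembly(asm, acts, gaps = gaps)
  expect_equal(cl$assembly$length, 125L)
  expect_equal(cl$post_stats$n_gaps, 0L)
  expect_equal(cl$assembly$seq,
               paste0(substr(asm$seq, 1, 10), acts$replacement_seq,
                      substr(asm$seq, 121, 130)))
})

test_that("multi-gap patching is order-independent and localized", {
  set.seed(81)
  seq <- paste0(random_seq(100), strrep("N", 10), random_seq(100),
                strrep("N", 20), random_seq(100))
  asm <- tibble::tibble(scaffold = "s", seq = seq, length = nchar(seq))
  gaps <- find_gaps(asm)
  reps <- c(random_seq(95), random_seq(130))
  acts <- tibble::tibble(
    gap_id = gaps$gap_id, scaffold = "s",
    replace_start = gaps$start - 50L, replace_end = gaps$end + 50L,
    replacement_seq = reps, status = "closed", coverage = 1L,
    pathway = "unsplit", used_fallback = TRUE, n_dropped_columns = 0L
  )
  out1 <- patch_assembly(asm, acts, gaps = gaps)$assembly$seq
  out2 <- patch_assembly(asm, acts[2:1, ], gaps = gaps)$assembly$seq
  expect_identical(out1, out2)
  # untouched regions are preserved
  expect_identical(substr(out1, 1, 50), substr(seq, 1, 50))
  expect_identical(substring(out1, nchar(out1) - 49), substring(seq, nchar(seq) - 49))

  # overlapping intervals are rejected
  bad <- acts
  bad$replace_end[1] <- bad$replace_start[2] + 1L
  expect_error(patch_assembly(asm, bad), class = "spanfill_validation_error")
})

test_that("closing an already-patched assembly closes nothing further", {
  cfg <- sim_config(seed = 91, genome_bp = 2e5, n_scaffolds = 1, depth = 8,
                    gap_sizes = c(10, 100, 400, 3000))
  truth <- sim_genome(cfg)
  gp <- sim_gapped_assembly(truth, cfg)
  rd <- sim_reads(truth, gp$gap_truth, cfg)
  sam <- tempfile(fileext = ".sam")
  writeLines(rd$sam, sam)
  aln <- read_alignments(sam)
  cl <- close_assembly_gaps(gp$assembly, aln)
  expect_equal(glance(cl)$n_closed, glance(cl)$n_gaps)
  cl2 <- close_assembly_gaps(cl$assembly, aln)
  expect_equal(glance(cl2)$n_gaps, 0L)
  expect_identical(cl2$assembly$seq, cl$assembly$seq)
})

test_that("tidy and glance expose the closure report", {
  asm <- tibble::tibble(
    scaffold = "s",
    seq = paste0(strrep("A", 60), strrep("N", 10), strrep("C", 60)),
    length = 130L
  )
  gaps <- find_gaps(asm)
  acts <- tibble::tibble(
    gap_id = "s_gap001", scaffold = "s", replace_start = 10L, replace_end = 120L,
    replacement_seq = random_seq(110), status = "closed", coverage = 2L,
    pathway = "unsplit", used_fallback = FALSE, n_dropped_columns = 0L
  )
  cl <- patch_assembly(asm, acts, gaps = gaps)
  td <- tidy(cl)
  expect_named(td, c("gap_id", "scaffold", "class", "status", "pathway",
                     "coverage", "old_len", "new_len"))
  expect_equal(td$class, "small")
  gl <- glance(cl)
  expect_equal(gl$n_closed, 1L)
  expect_equal(gl$mean_coverage_closed, 2)
  expect_output(print(cl), "1 of 1 gaps")
})

test_that("gap_size_class bins nominal sizes with 10% tolerance", {
  expect_equal(gap_size_class(c(10, 100, 400, 3000, 5000, 10000)),
               c("small", "small", "small", "large", "large", "large"))
  expect_equal(gap_size_class(c(395, 440, 2700, 10900, 777)),
               c("small", "small", "large", "large", "other"))
})
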