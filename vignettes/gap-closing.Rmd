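---
title: "Closing assembly gaps with spanning long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closing assembly gaps with spanning long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spanfill)
```

## The problem

Draft genome assemblies built from linked reads and proximity ligation are
highly contiguous at the scaffold level but riddled with gaps: runs of `N`
standing in for sequence the assembler could order but not reconstruct.
Linked-read assemblers emit these gaps at *fixed nominal sizes* — 10, 100 or
400 bp for short unknowns and 3000, 5000 or 10000 bp for long ones — so gap
length is a size-class label, not a measurement. A modest amount of noisy
long-read data (a few-fold coverage from a single nanopore flowcell) is
enough to reconstruct most of the missing sequence, because individual reads
of ~6.5 kb mean length frequently span an entire gap together with unique
anchoring sequence on both sides.

`spanfill` implements that procedure as a reusable toolkit, together with
the continuity statistics used to judge it (contig/scaffold N50) and a
windowed-heterozygosity / runs-of-homozygosity (ROH) profiler for the
population-genetic follow-up analyses such assemblies support.

## The closure procedure

For every maximal N-run of length ≥ `min_gap_length` (default 10), evidence
is collected from coordinate-mapped long reads via two pathways:

* **Unsplit pathway.** A read whose single, unsplit alignment covers the gap
  *plus at least `flank` bp (default 50) of aligned sequence on each side*
  qualifies. The read subsequence between the liftover images of
  `gap_start − flank` and `gap_end + flank` is extracted, so each piece of
  evidence carries read-derived flanks. Liftover walks the CIGAR
  operation-by-operation; a position inside a deletion maps to the read
  coordinate immediately after it.
* **Split pathway** (gaps ≥ `min_split_gap`, default 3000 bp). Aligners
  usually refuse to thread a read through several kilobases of `N`; instead
  they split it into a primary and a supplementary record mapping to either
  side of the gap. A split group qualifies when exactly one part ends within
  `max_side_dist` (default 100 bp) of the left gap edge, exactly one part
  starts within the same distance of the right edge, both on the same strand
  and in consistent read order. The read interval strictly between the two
  mapped parts — the unmapped middle — is the evidence.

All coordinates are 0-based half-open internally; SAM positions are
converted at the parser boundary, which removes every off-by-one ambiguity
from the CIGAR arithmetic. Reverse-strand records are normalised at parse
time so that every extracted sequence is in reference orientation; this is
the only convention under which flank concatenation is well defined.

Per gap, the pooled evidence is resolved as follows:

* **No evidence** — the gap stays `uncovered`.
* **One read** — single-read fallback: the raw extracted sequence is used
  directly (unsplit evidence already carries read flanks; a split middle is
  wrapped in the ≤ 50 bp reference flanks). The fallback is recorded per gap
  (`used_fallback`) so reports can separate consensus-backed patches from
  single-read ones, and it applies to both pathways.
* **Two or more reads** — a multiple alignment is built and a majority
  consensus called (below). Reference flanks join the alignment per pathway:
  as two separate anchor rows for unsplit evidence, whose rows already
  contain read-derived flank copies; concatenated onto each unmapped middle
  for split evidence, whose rows would otherwise have nothing in common at
  their ends.

Closed gaps are patched by replacing the interval
`[gap_start − |left flank|, gap_end + |right flank|)` with the replacement
sequence, right-to-left within each scaffold so earlier coordinates stay
valid. We replace the full flanked interval (the consensus includes
flank-anchored ends) rather than preserving the assembly flanks; with clean
data the two choices coincide, and replacing the interval keeps the
procedure self-consistent when the consensus ends disagree with the
assembly.

## Multiple alignment and consensus

The MSA is a deterministic center-star construction: the sequence with the
maximal summed pairwise global-alignment score is the center (lowest input
index on ties), every other sequence is aligned to it, and the pairwise
alignments are merged under "once a gap, always a gap". Pairwise scores are
match +1, mismatch −1, gap open −2, gap extend −1 (a length-L gap costs
2 + L); the pairwise step itself is delegated to
`Biostrings::pairwiseAlignment`. Center-star is not an optimal MSA, but at
per-gap coverage of a handful of near-identical sequences it is accurate,
fast, and — unlike heuristic MSA tools — bit-reproducible, which the
determinism guarantees of the toolkit rely on.

The consensus rule is per-column plurality with tie-column removal:

* a strict plurality base is emitted;
* a plurality gap emits nothing (and is *not* counted as a dropped column);
* a tie for the top count emits nothing, and is counted in
  `n_dropped_columns` when at least two of the tied symbols are bases.

One deliberate refinement: **leading and trailing gaps of a row do not
vote**. A 50 bp flank-anchor row is "absent", not "deleted", across the gap
interior, exactly as consensus tools treat sequence ends. Without this rule
the two anchor rows would tie against the two read bases in every interior
column at coverage 2 and veto the whole patch. Columns a row genuinely
spans, including interior deletions, vote normally.

A consensus shorter than the two flanks plus one base means the evidence
could not resolve any interior sequence; the gap is reported `ambiguous` and
left open rather than patched with flank debris.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_gap_length` | 10 bp | smallest N-run treated as a gap; matches the smallest fixed assembler gap size |
| `flank` | 50 bp | anchoring requirement and reference-flank width |
| `min_split_gap` | 3000 bp | smallest gap handled by the split pathway; gaps below it are closed by unsplit reads only |
| `max_side_dist` | 100 bp | how close a split part must end to the gap edge; split parts typically clip exactly at the edge, but noisy ends need tolerance |
| `contig_break_n` | 10 bp | N-run length that breaks scaffolds into contigs for the continuity statistics; exposed because different statistics scripts use different cutoffs |
| MSA scores | +1/−1/−2/−1 | fixed defaults, exposed on every closure function |

`max_side_dist` and the handling of >2-part split groups (skipped with a
warning as ambiguous) are genuine open choices — nothing in the procedure's
definition pins them down — and are therefore parameters, not constants.
No minimum-coverage filter beyond ≥ 1 read is imposed: observed per-gap
coverage is an outcome, not a threshold.

## Heterozygosity windows and ROH

`read_het_sites()` takes standard VCF genotypes (a site is heterozygous when
the sample's GT has two called, distinct alleles; indels excluded by
default; optional depth and quality filters mirror the usual `DP > 10`,
`QUAL > 20` site filtering). `het_windows()` counts het sites in 1 Mb bins —
an intermediate scale for ROH — normalising truncated final bins by their
true width. `proxy_roh_from_windows()` merges maximal runs of windows at or
below `max_het_per_kb` into ROH-like segments; the default threshold of
0.1/kb is a knob of this package, chosen an order of magnitude below a
typical ~1/kb mammalian background so that only genuinely depleted windows
qualify. The proxy has window resolution: tracts shorter than a bin are
invisible and boundaries are accurate to ±1 bin, which the tests assert
rather than assume.

`read_roh_segments()` parses BCFtools-RoH `RG` tables (we consume that
tool's output; we do not re-derive its HMM) and `roh_summary()` reports
counts, bp and genome fractions in the standard length classes. Boundaries
are half-open — `[10 kb, 100 kb)` short, `[100 kb, 1 Mb)` medium,
`[1 Mb, ∞)` long — so a segment of exactly 100 kb is medium; only the top
boundary's closure is fixed by the class names, the inner assignments are
this package's convention and are stated in the report header. Segments
under 10 kb are tallied separately as `sub` and excluded from the three
classes.

## The simulator

`sim_fixture()` generates everything the pipeline consumes, so every stage
is testable without downloads: an i.i.d. truth genome at a configurable GC
fraction (default 0.42, typical for mammalian genomes); a gapped assembly
in which each planted gap replaces a truth segment of exactly its nominal
size (so the truth table is also the answer key); log-normal reads (mean
6528 bp, `sdlog` 0.5) with per-base substitution/insertion/deletion errors;
truth alignments emitted directly as SAM — unsplit records whose CIGAR runs
through small gaps as `M`, split primary + supplementary pairs around gaps
≥ 3 kb, no aligner required; and VCFs whose heterozygous sites follow a
Poisson process outside planted ROH tracts and vanish inside them.

What it does **not** emulate: mapping error and mismapping, homopolymer-
biased nanopore errors, chimeric reads, quality-score variation, repeat
structure, or diploidy in the reads. Passing tests therefore demonstrate
that the algorithms are correct under their stated contracts — coordinate
arithmetic exact, consensus behaviour as specified, recovery complete when
alignments are truthful — not that real aligner output is this clean. All
randomness flows from one master seed through fixed per-stage sub-seeds;
outputs are byte-identical across runs, which is itself under test.

## Problem sizes and numerical choices

The test suite and the acceptance script exercise the pipeline at a 2 Mb /
4-scaffold genome with 60 gaps (10 per fixed size class), depth 5 of
error-free reads for exact-recovery checks and depth 8 at 3%/1%/1%
sub/ins/del for the noisy-recovery checks — large enough that every size
class and both pathways occur many times, small enough to run comfortably
on a laptop. Heterozygosity checks use a 10 Mb scaffold at 1 het/kb
background with planted 50 kb / 500 kb / 2 Mb tracts.

Degenerate inputs are contracts, not surprises: empty assemblies, zero-gap
scaffolds, empty evidence sets, empty VCFs and header-only ROH tables all
return well-typed empty results or fail with classed validation errors;
overlapping patch intervals are a hard error; ambiguity codes other than N
are coerced to N on input (with a warning count) because the consensus
alphabet is `{A,C,G,T}`.

## Limitations

* Center-star MSA with unit-ish scores is deliberately simple; highly
  divergent evidence (mis-mapped reads) is more likely to end `ambiguous`
  than to be reconciled. That is the conservative failure mode.
* The split pathway requires exactly one anchor on each side; tandem or
  >2-part split reads are skipped as ambiguous rather than adjudicated.
* Quality scores are ignored throughout; the consensus is unweighted.
* The ROH proxy is window-resolution and single-sample; it complements, and
  does not replace, HMM-based ROH callers whose output this package parses.
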