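Package: spanfill
Title: Close Assembly Gaps with Spanning Long Reads and Profile Runs of
    Homozygosity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to close N-run gaps in draft genome assemblies using
    long sequencing reads. Locates gaps, collects gap-spanning evidence
    from read alignments via two pathways (unsplit flank-anchored reads,
    and split reads whose unmapped middle bridges large gaps), pools the
    evidence into a center-star multiple alignment, calls a tie-dropping
    majority consensus anchored by reference flanks, and patches the
    assembly. Also computes assembly continuity statistics (contig and
    scaffold N50), windowed heterozygosity from VCF genotypes as a proxy
    for runs of homozygosity, and length-class summaries of ROH segment
    tables. Includes a deterministic simulator producing truth genomes,
    gapped assemblies, noisy long reads with truth alignments, and VCFs
    with planted ROH tracts, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    Rsamtools,
    stats,
    stringr,
    tibble,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
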