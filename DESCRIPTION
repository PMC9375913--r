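Package: orfvar
Title: Variant Annotation Across Canonical and Alternative Open Reading Frames
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates genomic variants against every open reading frame (ORF)
    hosted by a transcript, not just the reference-annotation coding sequence.
    Alternative ORFs -- upstream, downstream, or overlapping the canonical CDS
    in a different reading frame -- receive the same consequence calling
    (SnpEff-style effect terms and the four-level modifier/low/moderate/high
    impact scheme) as canonical ones, so a variant that is a 3'UTR modifier for
    the annotated protein can surface as a stop-gain in a dual-coding region.
    Includes per-variant maximal-impact summary tables, a binomial z-score test
    for variant clustering in the overlap of two coding regions, a sliding-window
    relative-impact profile along a gene, and a seeded synthetic-gene simulator
    with a brute-force re-translation oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    methods,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
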