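Package: splicecons
Title: Splice-Site Conservation and Gene-Structure Evolution from
    Multiple Genome Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scores the evolutionary conservation of gene structure by
    classifying every splice site of a set of transcripts across the
    species of a multiple genome alignment (MAF, human-referenced),
    rolling site calls up into graded transcript-level conservation
    (present, intermediate fractions, complete), and testing whether a
    target transcript set (for example, disease-associated lncRNAs) is
    less structurally conserved than a background set, independently per
    species with Fisher's exact test. Includes a synthetic-data
    generator that simulates splice-site turnover along a phylogeny with
    closed-form expected rates, so every stage of the pipeline can be
    validated against scripted ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
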