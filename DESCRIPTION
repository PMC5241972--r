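Package: recweave
Title: Assembly Reconciliation, Linkage-Map Anchoring and Tandem-Repeat
    Analysis for Draft Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for weaving several draft genome assemblies of the same
    individual into one improved assembly, guided by a genetic linkage map and
    whole-genome multiple alignments (MAF): containment and length filtering,
    linkage-conflict detection and scaffold splitting, gap closing and scaffold
    joining from donor assemblies, and ordering/orienting scaffolds into linkage
    groups. Also provides a score-thresholded tandem-repeat detector (wraparound
    dynamic programming, unit sizes 1-50 bp), heterozygous tandem-repeat calling
    from filtered indel variants, contig-terminus fragmentation attribution, and
    a seeded simulator producing truth-known genomes, diploid variant sets,
    fragmented draft assemblies, alignments and linkage maps for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    S4Vectors,
    seqinr,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
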