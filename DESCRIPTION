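Package: contigqc
Title: Post-Assembly Diagnostics for Long-Read Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-contig diagnostic statistics and triage for draft genome
    assemblies: GC content, read depth at two mapping-quality strata, unique
    k-mer fraction, telomere-motif enrichment, masked fraction and contiguity
    metrics; depth-bimodality sex-chromosome assignment and collapsed-repeat
    detection; MinHash (Mash) distance contaminant screening with a
    longest-aligned-region fallback; dual-caller variant consensus with
    quality-dip thresholding, genic partitioning, indel frame analysis and
    SNP-density summaries; phase-block summaries from phased VCFs; and
    comparative BUSCO completeness analysis with upset intersections and
    ancestral-loss adjustment. Includes a synthetic-data generator that
    emulates a diploid genome with known ground truth so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    tools,
    utils,
    methods,
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    vcfR,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
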