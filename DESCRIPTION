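Package: quantalign
Title: Hybrid Quantized Alignment of Nanopore Long Reads for Structural
    Variant Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aligns nanopore long reads by translating basecalled nucleotide
    sequences into ternary current-level ('HQ3') sequences through a Q-mer
    pore model and re-aligning them within extended regions of interest found
    by a coarse nucleotide alignment. Includes an alphabet-generic minimizer
    seed-chain-extend alignment engine, alignment-quality metrics (well-aligned
    fraction, normalized edit distance and alignment length), a split-read and
    CIGAR-based structural-variant extractor, Truvari-style call matching with
    breakpoint score and length similarity, precision/recall/F1 and a union
    call model, and a synthetic long-read simulator whose substitution errors
    are biased toward Q-mers with similar current levels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    vcfR,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
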