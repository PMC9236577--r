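Package: clonedecomp
Title: Joint Clonal Deconvolution of SNVs, Copy Number and Structural
    Variants into Tumor Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs tumor clonal lineage trees from multi-sample bulk
    DNA sequencing variant calls. Single-nucleotide variants, allele-specific
    segment copy numbers and structural-variant breakpoints are jointly
    deconvolved into integer clone profiles, per-sample clone frequencies and
    a binary phylogeny by coordinate descent that alternates a frequency
    linear program with a phylogeny-constrained integer linear program under
    a Dollo parsimony model on breakpoints and SNVs. Includes a clonal
    evolution simulator with read-count noise, variant subsampling with
    post-hoc assignment of held-out variants to tree edges, and evaluation
    metrics (profile and frequency RMSE after clone matching, normalized
    Robinson-Foulds distance, co-clustering average precision).
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
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    ape,
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
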