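Package: mirforge
Title: Conservation-Independent Discovery of Plant miRNAs from Small-RNA
    Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for discovering microRNAs from multi-library
    small-RNA sequencing data mapped to a transcript (EST) reference, without
    relying on cross-species conservation. Reads are trimmed, filtered and
    collapsed; candidate precursor windows around mapped loci are folded with
    ViennaRNA and reduced to stem-loops; a duplex-position classifier scores
    the placement of the mature miRNA within its hairpin on a 0-100 scale;
    expression-profile rules (processing precision, star evidence) refine the
    candidate set. Downstream stages assign conserved families by ungapped
    homology to a mature-miRNA reference, call differential expression between
    libraries with the pooled two-proportion (Kal) z-test under
    Benjamini-Hochberg FDR control, predict targets by seed-weighted
    complementarity with a duplex free-energy ratio gate, and test GO-Slim
    term enrichment with the hypergeometric distribution. A seeded synthetic
    data generator with a ground-truth manifest makes every stage testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    S4Vectors,
    randomForest,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
SystemRequirements: ViennaRNA (RNAfold and RNAduplex on the PATH)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
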