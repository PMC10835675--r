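Package: depthformer
Title: Dual-Strand Transformer Regression of Probe Sequencing Depth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts hybridization-capture sequencing depth per
    oligonucleotide probe from the probe sequence alone. Probes are
    tokenized into overlapping k-mers for both the forward strand and its
    reverse complement; each strand is encoded by an independent
    transformer encoder stack and the pooled representations are
    concatenated and passed through a feed-forward head that regresses
    log10-scale read depth. Includes panel input/output (FASTA plus depth
    tables), depth normalization, cross-validation with factor-of-N
    accuracy metrics, model interpretation via attention-score
    aggregation and integrated gradients, extreme-depth k-mer enrichment
    analysis, and a synthetic panel simulator with a known
    sequence-to-depth law for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma,
    withr
SystemRequirements: C++17
Config/testthat/edition: 3
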