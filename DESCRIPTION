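Package: cnvalleles
Title: Copy-Unit Allele Inference at Copy Number Variable Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simultaneous estimation of copy-unit allele sequences and per-sample
    allele proportions at a copy number variable (CNV) locus from per-site read
    base counts. Implements a latent-Dirichlet-allocation-style generative model
    fitted by variational Bayesian EM, model selection over the number of alleles
    by the evidence lower bound, simulators for benchmark designs, allele
    concordance metrics (precision, recall, F-measure), conversion of allele
    proportions to integer copy numbers with a trio heredity-consistency check,
    and readers/writers for base-count tables, samtools-mpileup text, and allele
    FASTA.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
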