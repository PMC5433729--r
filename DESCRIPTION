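Package: keycontrib
Title: Identification of Key Contributors in Structured Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised identification of key contributors, the individuals
    that capture most of the variance of a genomic relationship structure.
    Builds identity-by-descent (IBD) genomic relationship matrices from phased
    haplotypes by hash-based segment detection, determines the number of
    significant eigencomponents by Horn's parallel analysis, scores every
    individual by its correlation with the retained standardized
    eigenvectors, and embeds the scores in a k-nearest-neighbour population
    network. Includes reference-set selection strategies for phasing and
    imputation panels (key contributors, greedy relationship capture,
    pedigree marginal contributions, random), haplotype switch-error
    evaluation, and a gene-dropping simulator of a five-generation livestock
    breeding design with exact ancestry tracking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml,
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
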