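Package: specgwas
Title: Bayesian Multiphenotype Genome-Wide Association for Hyperspectral
    and Growth Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spike-and-slab Bayesian whole-genome regression (univariate and
    bivariate BayesC) for genome-wide association analysis of manually measured
    growth traits and hyperspectral phenotypes in crop diversity panels.
    Includes marker quality control and LD pruning, hyperspectral cube masking
    and a data-driven registry of named spectral indices, genomic heritability
    and genomic correlation estimation from MCMC draws, posterior-inclusion-
    probability marker selection with gene-window annotation from GFF3, a
    synthetic-data generator with known ground truth for validation, and
    Manhattan/PheWAS visualisation of multiphenotype results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    grDevices,
    jsonlite,
    yaml,
    coda,
    ggplot2,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
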