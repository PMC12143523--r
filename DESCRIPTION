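Package: GeoAssign
Title: Continuous Spatial-Genetic Assignment of Geographic Origin from SNP Genotypes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting the geographic origin (latitude, longitude)
    of individuals from biallelic SNP genotypes when genetic variation is
    continuous across the landscape (isolation by distance). Implements five
    continuous assignment methods behind a common interface: a genetic
    nearest-neighbour averager, genomic prediction of coordinates by gBLUP
    with REML variance components and prediction error variances, direct
    Gaussian-process regression of coordinates on genotypes with an RBF
    kernel and random-search hyperparameter tuning, grid-based
    Gaussian-process modelling of per-SNP allele-frequency surfaces
    (Matern 5/2) with Hardy-Weinberg maximum-likelihood cell assignment,
    and a feedforward neural-network ensemble. Includes leave-one-out
    cross-validation, accuracy summaries (Haversine distances, Pearson
    correlations, relative errors), two-tier IQR-based outlier detection
    against method-specific 95% distance radii, and a simulator of
    georeferenced SNP landscapes with clinal allele-frequency surfaces,
    Hardy-Weinberg genotype sampling, plastid-like haploid markers and
    injected translocations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    tools,
    Rcpp,
    jsonlite,
    vcfR
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
NeedsCompilation: yes
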