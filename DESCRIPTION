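Package: magicGP
Title: Genomic Prediction in Multi-Parent (MAGIC) Populations with
    Genotype-by-Environment Interaction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for genomic prediction in
    eight-way MAGIC (Multi-parent Advanced Generation Inter-Cross)
    populations of inbred (doubled-haploid) lines. Provides a funnel-cross
    simulator with Haldane meiosis and multi-environment alpha-lattice
    trials; lattice mixed-model adjusted means and broad-sense
    heritability; genomic relationship (GBLUP) and Gaussian kernels with
    empirical-Bayes bandwidth selection; Gibbs samplers for whole-genome
    regression (BayesA, BayesB, Bayesian LASSO) and for single- and
    multi-environment kernel models with main and environment-specific
    genetic effects; training-population optimization (CDmean, PEV,
    rScore, entry-to-nearest-entry on modified Rogers distances); and
    cross-validation machinery (training-size sweeps, leave-one-out,
    CV1/CV2) with Welch comparisons, PCA and linkage-disequilibrium decay
    profiling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    lme4,
    jsonlite,
    yaml,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    vcfR,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'magicGP-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'evaluate.R'
    'founders.R'
    'funnel.R'
    'geneticMap.R'
    'gp-models.R'
    'io.R'
    'kernels.R'
    'lattice.R'
    'meiosis.R'
    'population.R'
    'tp-optim.R'
    'trait.R'
    'trial.R'
    'wgr.R'
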