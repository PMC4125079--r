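Package: polyadapt
Title: Detecting Polygenic Adaptation from GWAS Loci and Population Allele Frequencies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests for polygenic adaptation acting on the genetic basis of a
    quantitative trait, using GWAS effect sizes and allele frequencies across
    many populations. Population mean genetic values are modelled under a
    multivariate normal drift null whose covariance is estimated from
    genome-wide SNPs matched to the GWAS loci on minor allele frequency,
    imputation status and background-selection (B value) bins. Provides the
    Q_X excess-variance statistic and its variance/covariance (F_ST-like and
    LD-like) decomposition, environmental-correlation tests on whitened
    genetic values with matched-SNP empirical null distributions, conditional
    multivariate-normal Z-scores for localizing signals to populations or
    regions, selection power simulations by perturbation of neutral
    frequencies along an environmental gradient, and a synthetic fixture
    generator for the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    MASS,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    jsonlite
Config/testthat/edition: 3
biocViews: PopulationGenetics, GenomeWideAssociation, StatisticalMethod
RoxygenNote: 7.3.3
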