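Package: herdblup
Title: Pedigree, Genomic and Single-Step BLUP Evaluation for Dairy Herd
    Lactation Records
Version: 0.1.0
Authors@R:
    person("herdblup", "authors", email = "devnull@example.org",
           role = c("aut", "cre"))
Description: Genetic evaluation of repeated 305-day lactation records under a
    repeatability animal model solved by Henderson's mixed-model equations,
    with three interchangeable relationship structures: the pedigree numerator
    relationship matrix (pBLUP), a VanRaden genomic relationship matrix among
    genotyped animals (GBLUP), and the single-step H matrix combining both
    (ssGBLUP).  Includes SNP quality control (map location, autosome set,
    minor allele frequency, Hardy-Weinberg equilibrium), a lactation-count
    threefold cross-validation design with accuracy and dispersion-bias
    statistics, and a gene-dropping herd simulator that provides pedigree,
    genotypes, repeated phenotypes and known true breeding values for
    validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
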