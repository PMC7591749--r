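Package: sdyped
Title: Copy-Number Genotyping and Autosomal Inheritance Analysis for the
    Salmonid Sex-Determining Gene sdY
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for resolving discordance between phenotypic sex and the
    sdY DNA marker in Atlantic salmon and other salmonids. Implements qPCR
    delta-delta-Ct fold-change computation and integer sdY copy-number
    calling, exclusion-based parentage assignment from microsatellite
    genotypes, a Mendelian model of autosomal sdY pseudocopy inheritance
    with Monte-Carlo chi-squared goodness-of-fit tests, and per-family
    chi-squared linkage scans of binary traits (sex, sdY discordance)
    against transmitted parental SNP alleles. A synthetic-data generator
    reproduces the statistical structure of pedigree-controlled cross
    designs (gene-drop meiosis under the Haldane map function, replicate
    qPCR noise) so that every stage of the pipeline can be exercised and
    validated without access to real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
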