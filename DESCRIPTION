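Package: osgs
Title: Origin Specific Genomic Selection for Bi-Parental Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitions genomic-prediction marker effects in a bi-parental
    cross by the parental origin of the favorable allele and selects on a
    weighted rank index of the two origin-specific breeding-value components
    (origin specific genomic selection, OSGS). Provides origin recoding of
    IUPAC marker tables with flanking-average imputation, a spectral-REML
    ridge-regression BLUP of marker effects, sign-based partitioning into
    primary- and secondary-parent components, rank-index selection, and a
    meiosis-level stochastic simulator of introgression breeding programs
    (F2-, BC1- and reverse-BC1-derived populations, single-seed descent,
    double haploids, recurrent selection) with the associated favorable-allele
    and breeding-value outcome metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
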