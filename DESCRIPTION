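Package: hemotyper
Title: Blood Group Phenotype Inference from Unphased Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint haplotype phasing and blood group phenotype calling from
    unphased genotype data against curated haplotype tables. For each gene the
    engine enumerates all assignments of heterozygous variants to the two
    chromatids, scores every configuration by 1-nearest-neighbour Hamming
    distance to the known phenotype-defining haplotypes, and reports the
    maximum-parsimony diplotype call with ranked alternatives and explicit
    ambiguity flags. Includes readers for a VCF subset and a simple tabular
    genotype dialect, a haplotype-table format with validation diagnostics,
    a planted-diplotype simulator with configurable noise, missingness and
    sparse-panel regimes, and cohort-level accuracy evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
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
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
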