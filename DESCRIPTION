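Package: gbsparent
Title: Parentage Assignment from Low-Depth Genotyping-by-Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns parentage from per-SNP allele read counts produced by
    low-depth genotyping-by-sequencing (GBS). At low read depth a heterozygote
    may be observed as a homozygote, so classical exclusion methods fail.
    gbsparent models the allele-sampling process (binomial, beta-binomial or
    Markov 'modified-p' reads), computes depth-aware expected mismatch rates
    for parent-offspring pairs and trios, and scores candidate parents by the
    excess mismatch rate (observed minus expected) together with genomic
    relatedness, bootstrap support for close candidates, and trio consistency
    checks (trio excess mismatch and parent-relatedness versus offspring
    inbreeding). Includes readers for Tassel/UNEAK hmc tables and VCF allelic
    depths, overdispersion-parameter estimation from accepted trios, and a
    pedigree/read simulator for validation.
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
    readr,
    rlang,
    stats,
    tibble,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
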