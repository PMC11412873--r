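Package: cryocomp
Title: Comparative Genomic Signatures of Psychrophilic Fungi
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the comparative-genomics signatures used to characterise
    cold-adapted (psychrophilic) fungi against background lifestyles:
    orthogroup expansion/contraction scoring from OrthoFinder-style gene-count
    tables via trimmed-mean standardisation and a Welch-type t statistic,
    species clustering on correlation distance, genome and third-codon-position
    (GC3) base composition with ANOVA/Tukey group comparisons, sliding-window
    repeat-induced point mutation (RIP) index scanning with large RIP-affected
    region (LRAR) calling, and canonical k-mer spectrum diagnostics of ploidy
    and heterozygosity. Includes seeded synthetic-data generators that plant
    known expansions, RIP-mutated repeat regions, GC3 levels and heterozygous
    diploid k-mer spectra, so every analysis stage can be validated against a
    known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
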