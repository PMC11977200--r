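Package: karyomorph
Title: Karyotype Morphometrics and Rearrangement Inference for Clawed Frogs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A comparative-cytogenetics toolkit for allopolyploid clawed
    frogs (Xenopus) and similar systems. Computes chromosome morphometrics
    (relative length, arm ratios, centromeric index) from per-chromatid arm
    measurements, classifies chromosomes into Levan categories, aggregates
    medians and interquartile ranges across metaphases, and tests homeolog
    divergence by one-way ANOVA with Tukey contrasts. Assigns measured
    chromosomes to a reference karyotype template by globally optimal
    bipartite matching, infers interchromosomal rearrangements
    (translocations and end-to-end fusions with centromere fate) and
    pericentromeric inversions from FISH marker maps, summarises rDNA/NOR
    FISH signal patterns, and counts minimum NOR relocation events on a
    species tree by uniform-cost parsimony. A seeded simulator generates
    metaphase measurement tables, marker-map rearrangement scenarios, and
    FISH signal tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
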