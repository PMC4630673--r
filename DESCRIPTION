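Package: bemadapt
Title: Quantitative Analysis of Evolutionary Adaptation to Loss of the
    Yeast Polarity Scaffold Bem1
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing experimental evolution of budding yeast
    lineages recovering from deletion of the polarity scaffold gene BEM1.
    Estimates population growth rates from count-time series and cell-size
    modes from Coulter-style size samples, identifies candidate adaptive
    mutations by comparing ancestor and evolved variant tables against an
    annotated genome (non-synonymous and promoter substitutions), tracks
    selective sweeps from Sanger peak-height allele fractions and infers
    the temporal order of mutations, summarises spore-grid survival and
    colony sizes, represents the four-locus genotype hypercube with
    per-genotype fitness to classify epistasis and enumerate selectively
    accessible mutational trajectories, and simulates the serial-dilution
    evolution protocol to estimate the probability of each mutational
    order. A seeded synthetic-data module generates every input the
    pipeline consumes, with ground truth stored alongside for estimator
    validation.
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
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
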