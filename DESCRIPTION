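Package: mtpool
Title: Multipartite Structure of Plant Mitochondrial Genomes from
    Repeat-Mediated Recombination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the multipartite structure of circular
    plant mitochondrial genomes. Detects large, short and tandem repeats by
    genome self-comparison; partitions a repeat family's progenitor copy
    into maximal shared segment blocks and infers the derivation order of
    copies; enumerates homologous repeat pairs and simulates the
    repeat-mediated recombination events (fission across direct pairs,
    inversion across inverted pairs) that generate subgenomic circles and
    isometric master isomers, closing over events to build the molecular
    pool; accounts genome composition over annotation tracks and tests
    uniformity of genomic positions on the circle. Includes a synthetic
    genome generator with planted repeat structure so the whole pipeline is
    testable without external data, and ships the published repeat
    annotation of the soybean mitochondrial genome as a worked example.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    generics,
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
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
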