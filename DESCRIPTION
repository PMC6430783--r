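Package: secircuit
Title: Super-Enhancer Calling and Core Regulatory Circuitry Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tidyverse-native toolkit for enhancer-centred regulatory
    genomics: ROSE-style super-enhancer (SE) calling from H3K27ac ChIP-seq
    signal (TSS exclusion, peak stitching, input-subtracted ranking and the
    geometric inflection cutoff), hockey-stick normalization, classification
    of transcription-factor peaks into promoter/SE/typical-enhancer
    categories, promoter occupancy combinations for factor families,
    TF-overloaded and double-positive SE identification, RNA polymerase II
    pausing-index and metagene profiles, core transcriptional regulatory
    circuitry (CRC) reconstruction by motif scanning within SEs with maximal
    clique enumeration and co-expression ranking, and occupancy-stratified
    expression-response statistics. Ships a synthetic-data generator that
    plants ground-truth super-enhancers, co-localized TF peaks, Pol2 pausing,
    motifs and expression effects on a toy genome so that every stage of the
    pipeline can be exercised and validated end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    generics,
    withr,
    ggplot2,
    jsonlite,
    yaml,
    igraph,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
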