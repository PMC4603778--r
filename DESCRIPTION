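Package: clickdel
Title: Chemically Ligated DNA-Encoded Library Simulation and Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational substrate for DNA-encoded small-molecule libraries
    built by chemical (CuAAC "click") ligation of encoding tags, which leaves
    triazole linkages in the DNA backbone. Provides encoding-schema modelling
    for three-cycle combinatorial libraries, average-mass arithmetic for
    modified oligonucleotides and triazole ligation products, a stochastic
    model of polymerase read-through across triazole junctions (per-junction
    stalling, single-A skipping, +/-A stall artifacts), a synthetic selection
    and FASTQ read generator with planted high-affinity families, a junction-
    tolerant read decoder, and enrichment / building-block family analysis
    with cube-plot coordinates.
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
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
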