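Package: ndescreen
Title: Outgroup-Aware Annotation of Nicotine-Degrading Enzymes in
    Microbiota Sequence Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Annotates homologs of the five bacterial nicotine-degrading
    enzyme (NDE) families (NdhB, NdhL, NicX, NicA1, NicA2) in protein
    catalogs from genomes and metagenomes. Candidates from exact local
    alignment against curated reference panels are passed through
    identity, coverage and length gates, a score-ratio rule against
    outgroup negative controls, an automated long-indel screen, and a
    neighbor-joining patristic-distance filter. Downstream summaries
    report sequence and source counts, taxonomic composition at GTDB
    ranks, genus overlaps between enzyme families, and per-group sample
    prevalence. A sequence-family simulator with known ground truth
    supports benchmarking of the whole cascade.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
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
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
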