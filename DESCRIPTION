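Package: funnovel
Title: Phylogenetic Origin Mapping of Orthogroups on a Clade Ladder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns orthogroups to their phylogenetic origin node on a nested
    clade ladder from presence-absence patterns (an orthogroup is called novel
    at a clade when it is present in at least half the sampled species of every
    member phylum -- every member subphylum for terminal phyla -- and present in
    at most one species outside the clade), validates candidates against
    non-fungal homolog hit counts, tests annotation enrichment among novel
    orthogroups with an exact two-sided Fisher test and EASE-style term
    enrichment, summarizes protein-protein interaction connectivity of novel
    proteins, and classifies species by the joint presence of prokaryote- and
    eukaryote-derived gene copies. A seeded synthetic-data generator simulates
    gene gain with lossy retention on the ladder so every pipeline stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
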