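Package: looparch
Title: Structural Classification of Protein Loops by Flanking Secondary
    Structure Geometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts loops bracketed by secondary structure elements from
    protein structures, describes each loop by the geometry of its flanking
    elements (distance, hoist, packing and meridian angles) and its backbone
    conformation in a Ramachandran alphabet, clusters loops per type with a
    greedy density-search algorithm (fixed length) and with Markov Clustering
    over a loop-similarity graph (length categories), and assembles the
    resulting clusters into a four-level type/length/class/subclass hierarchy
    with size-ranked codes, consensus geometry and RMSD quality statistics.
    Includes a synthetic backbone generator so the whole pipeline can be
    exercised without external structure files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
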