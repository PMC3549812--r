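Package: reguide
Title: Reference-Guided Genome Reassembly from Colored de Bruijn Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reference-guided reassembly of a donor genome from error-free
    short-read k-mer spectra. Builds a colored reference/donor de Bruijn
    graph, condenses non-branching donor paths into contigs annotated with
    reference markers, and orders and merges contigs with a tau-gap
    message-passing algorithm (marker propagation, orphan pruning, forced
    merging). Includes a structural-variant simulator (insertions,
    deletions, duplications, translocations, SNVs) with an invertible event
    log, an idealized paired-end read generator, and assembly evaluation
    metrics (contig count, N50, max contig, accuracy).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
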