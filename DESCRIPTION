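Package: ismic
Title: Interpretive Structural Modeling and MICMAC Analysis of Expert Judgments
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the complete interpretive structural modeling (ISM)
    workflow for expert-elicited factor systems: ratification of a factor
    roster by panel vote, aggregation of per-expert pairwise V/A/X/O
    judgments into a structural self-interaction matrix (SSIM), conversion
    to a binary reachability matrix, transitive closure under explicit
    modes (full Warshall closure, single-pass, or as given), level
    partitioning by iterated top-element removal, conical matrix and
    hierarchical digraph construction with transitive reduction on the
    strongly-connected-component condensation, and MICMAC
    driving-dependence quadrant classification. Ships the printed tables
    of a published mass-gathering SOP-effectiveness study as plain-text
    fixtures, a seeded synthetic-data generator with known level structure
    for end-to-end validation, CSV readers and writers for every artifact,
    DOT export, and markdown reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
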