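Package: phylocompare
Title: Side-by-Side Comparison and Visualization of Phylogenetic Trees
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing two phylogenetic trees built on the same
    set of taxa. Computes per-node leaf-set similarity (Jaccard index over
    the leaves below each node) and the best corresponding node in the
    opposing tree, finds the rooting and leaf order of one tree that best
    matches the other, models viewport-driven collapsing of large trees,
    and renders single trees or side-by-side comparisons as deterministic
    SVG with a similarity colour scale. Includes a Newick parser/writer
    with an NHX-style extended dialect that round-trips visualization
    state, a seeded synthetic-tree generator with controlled perturbations
    (NNI moves, rerooting, child shuffles), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    optparse,
    stats,
    utils,
    withr
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
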