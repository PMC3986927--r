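Package: pmscreen
Title: Stress-Tolerance Profiling from Phenotypic Microarray Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for high-throughput phenotypic microarray
    (OmniLog/Biolog-style) redox kinetics: monotone smoothing of dye-conversion
    curves, percentage redox signal intensity (%RSI) scoring of strain stress
    tolerance against unstressed controls, ranking and tolerant/sensitive
    classification, log2-ratio profiling against a reference strain, and
    average-linkage (UPGMA) hierarchical clustering with centred Pearson
    distances, exported in Cluster 3.0/TreeView (CDT/GTR) and Newick formats.
    Includes a seeded synthetic-study generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    ape,
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
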