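Package: labmotif
Title: Network Motif Detection in Samples of Vertex-Labeled Directed Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects network motifs in a sample of directed simple graphs that
    share one set of pairwise-distinct vertex labels, as arises for effective
    connectivity networks over a fixed EEG electrode montage. Because vertices
    are labeled, two subnetworks are identical exactly when they have the same
    edge set, so motif detection reduces to exhaustive enumeration of connected
    induced subnetworks, counting occurrences across the sample, an analytic
    independent-edge (Erdos-Renyi) null model fitted to the sample's mean edge
    density, an exact one-sided binomial test of overrepresentation per
    subnetwork, and Holm step-down control of the familywise error rate.
    Includes a synthetic-sample generator with optional planted subnetworks,
    plain-text readers and writers for edge lists and labeled adjacency
    matrices, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
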