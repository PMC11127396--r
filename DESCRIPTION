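Package: clustermerge
Title: Consensus Merging of Clustering Results by Greedy Agreement Maximization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconciles several clusterings (partitions) of the same
    observations by greedily merging pairs of clusters within each partition
    so as to maximize the mean pairwise normalized mutual information (or
    adjusted Rand index) between partitions, stopping automatically when no
    merge improves the overall agreement. Also provides two hierarchical
    baseline mergers (bottom-up along a medoid tree, and merging by fraction
    of differentially expressed genes), evaluation utilities
    (agreement-with-truth curves, their area under the curve, average
    silhouette based output selection), and synthetic-data generators (a 2-D
    Gaussian-grid mixture and a Splatter-style negative binomial count
    simulator) so the full benchmark runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    limma,
    cluster,
    methods,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
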