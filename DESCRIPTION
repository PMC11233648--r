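Package: ccgnet
Title: Signed Functional Networks from Spike Trains via Jitter-Corrected
    Cross-Correlograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds signed, directed functional connectivity networks from
    binned multi-trial spike trains using jitter-corrected cross-correlograms
    with sharp-peak and sharp-interval detection, and analyses their topology:
    signed two- and three-node motif intensity Z-scores against nested
    randomized reference models (Erdos-Renyi, degree-preserving,
    pair-preserving and signed-pair-preserving), signed modularity with a
    modified Louvain community detection, multi-resolution consensus
    partitions, and module-versus-area agreement metrics (coverage, purity,
    adjusted Rand index). Includes a synthetic spike-train generator with
    planted ground-truth couplings for end-to-end validation, and the
    modified asymptotic test for comparing overlapping correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
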