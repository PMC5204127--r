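Package: confeax
Title: Conserved Feature Discovery and Coevolution Profiling in Divergent
    Protein Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: De novo discovery of short conserved regions (short linear
    motifs and small domains) in divergent protein families by
    expectation-maximization on position weight matrices with a
    repeats-allowed site model, followed by iterative refinement with
    internally built profile hidden Markov models (hit extension,
    progressive instance alignment, empirical Gumbel E-value calibration,
    search-to-convergence). Downstream, binary phylogenetic profiles of
    the discovered features across duplicated gene copies are correlated
    (Pearson) and clustered by average linkage on d = 1 - r to detect
    co-segregating feature sets that signal subfunctionalization after
    gene duplication. Includes a synthetic gene-family generator with
    full ground truth for benchmarking every stage.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    Biostrings,
    mclust,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
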