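Package: ampmock
Title: Mock-Community Validation of V1-V3 16S rRNA Amplicon Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to design balanced mock bacterial communities, simulate
    ground-truthed multi-sample 16S rRNA gene amplicon runs, and quantify how
    removal of cross-sample singleton and doubleton sequences affects
    sequencing error rates, OTU richness, alpha diversity, and taxonomic
    assignment. Implements equal-copy mock design arithmetic, exact-sequence
    dereplication with rarefaction and abundance filtering, ends-free global
    alignment to known reference sequences for per-base error estimation and
    reference-based chimera flagging, average-linkage OTU clustering with
    Chao, Shannon and inverse Simpson summaries, log-log cluster-size
    spectrum diagnostics with linear and lowess fits, and an end-to-end
    three-way (all / no singletons / no singletons and doubletons)
    validation report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
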