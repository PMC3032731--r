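Package: orthorank
Title: Ortholog Profiling and Process-Level Ranking of Model Organisms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies every protein of a reference proteome as ortholog,
    homolog or absent in each of a set of target organisms from pairwise
    alignment statistics (e-value, identity, coverage thresholds plus a
    composite orthology F-score), maps proteins to GO-slim terms and KEGG
    pathways, builds per-term presence/absence vectors over the pathway
    protein superset, and ranks organisms by Normalized Hamming Distance
    to the reference for each biological process. Includes a synthetic
    fixture generator with controlled ground truth for end-to-end testing,
    and reporting helpers (status tables, distance matrices, heat maps,
    clade-level rollups).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    pheatmap,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
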