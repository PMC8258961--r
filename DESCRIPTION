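Package: rasonet
Title: RASopathy Interactome and Phosphoproteomics Harmonization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds and analyzes protein-protein association networks seeded
    on the causative RASopathy proteins: neighborhood expansion from offline
    STRING-dialect association tables, interactome deduplication, per-seed
    overlap statistics, pairwise intersection histograms, syndrome
    partitions, and degree-based hub detection. Harmonizes heterogeneous
    phosphoproteomic and immunoblot measurements across organisms by
    alignment-based phosphosite coordinate transfer onto human sequences,
    assembles a site-by-syndrome log2 fold-change dysregulation matrix with
    explicit reported-unchanged states, assigns NS/NSML cluster labels, and
    produces a per-protein phosphosite census split by evidence throughput
    class. Includes a generic hypergeometric over-representation test with
    Benjamini-Hochberg control and a synthetic-data generator that plants
    known overlap structure, hubs, and dysregulation counts so every stage
    is testable without database access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
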