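Package: paleomito
Title: Ancient Mitochondrial DNA Consensus Calling, Haplogroup
    Classification and Population Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for clone-based ancient mitochondrial DNA analysis:
    reference-relative HVS1 haplotype representation and motif parsing,
    authentication of clone sequences (staff and carry-over contamination,
    miscoding-lesion typing), reproducibility-validated consensus haplotype
    calling, decision-table haplogroup classification from HVS1 motifs and
    coding-region SNPs, and multi-population comparison via shared-haplotype
    counts, permutation-tested pairwise FST, principal component analysis
    with Ward clustering, and inverse-distance-weighted geographic affinity
    surfaces.  A synthetic-data generator with known ground truth supports
    parameter-recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    geosphere
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
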