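Package: ribopause
Title: Codon-Resolution Ribosome Pausing and Co-IP Interactome Enrichment
Version: 0.1.0
Authors@R: person("ribopause", "authors", role = c("aut", "cre"), email = "maintainer@example.org")
Description: Tools to detect codon-level ribosome pausing from
    transcriptome-space ribosome-profiling alignments and to score
    co-immunoprecipitation interactomes from label-free quantification
    tables. Implements per-read-length P-site offset estimation, E/P/A-site
    codon assignment, a local-background pause z-score with calls at z >= 10,
    observed-versus-expected A-site codon occupancy, and a proteomics
    enrichment workflow (QC flag filtering, log2 transform, group validity
    filter, left-shifted normal imputation, Student's t-test). A synthetic
    data module generates ground-truth transcriptomes, footprint alignments
    and quantification tables so every stage is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
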