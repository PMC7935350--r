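Package: txintegrate
Title: Multi-Library De Novo Transcriptome Contig Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates per-library de novo transcriptome assemblies into a
    single non-redundant contig set. Implements reciprocal-best-hit seed
    selection against a reference protein database with HSP-coverage
    pre-filters, paralog extension, cross-library redundancy clustering under
    a bounded (2 bp) mismatch/gap tolerance with singleton rescue,
    taxonomy-based contamination filtering, self-BLAST isoform grouping,
    mutual-coverage evaluation between transcript sets, read-mapping-rate
    summaries, and pedigree-aware group-specific variant selection from
    per-accession VCFs. Ships a deterministic synthetic-data generator that
    emits every input format with a known ground-truth manifest.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    igraph,
    vcfR,
    tibble,
    dplyr,
    rlang,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
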