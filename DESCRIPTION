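Package: seqcurate
Title: Reproducible Curation of Public-Repository Sequences for a Target Locus
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An offline, deterministic pipeline for curating nucleotide
    sequence records downloaded from public repositories such as GenBank,
    built around a single target locus (by default the mitochondrial
    cytochrome-b gene). Records are parsed and normalised, RefSeq
    duplicates removed, taxonomy reconciled against a user-supplied
    synonymy table, and each sequence is oriented and trimmed against a
    reference locus by semi-global alignment, recovering submissions
    uploaded in backward-read format and extracting the locus from whole
    mitochondrial genomes. Conspecific sequences are multiply aligned,
    frame-breaking gaps resolved under the vertebrate mitochondrial code,
    and uncorrected pairwise divergences (p-distances, pairwise deletion)
    computed within species and genera. A divergence threshold (default
    3%) flags taxonomically conflicting sequences: conspecifics that are
    too divergent and heterospecifics that are too similar. Coverage
    profiling, best-region search, summary statistics, and a seeded
    synthetic-data generator with planted errors complete the toolkit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    ape,
    jsonlite,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
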