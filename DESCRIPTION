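Package: txmerge
Title: Merge De Novo Transcriptome Assemblies by Orthogroup Clustering and
    Read-Evidence Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Merges two or more de novo transcriptome assemblies into a single
    non-redundant assembly. Pooled contigs are grouped into orthogroups by
    Markov clustering of a canonical k-mer containment graph (inflation 4 by
    default, so transcript isoforms resist collapsing into one group), each
    contig is scored from paired-end read evidence (nucleotide fidelity, base
    coverage, pair order, and coverage-segmentation plausibility, combined as
    a geometric mean), and the highest-scoring contig per orthogroup is kept.
    Also provides assembly diagnostics: mapping rate, bottom-s MinHash sketch
    distances with classical MDS embedding, fragment-count TPM quantification,
    assembler-of-origin contribution and duplication reports, and a synthetic
    benchmark generator that emulates assembler-specific expression-dependent
    dropout, fragmentation, duplication, and chimera formation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Matrix,
    Rcpp,
    data.table,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
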