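Package: isoatlas
Title: Full-Length Transcriptome Reconstruction and Splicing Analysis from
    Long Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reference-based pipeline for building a non-redundant
    full-length transcriptome from long-read isoform sequencing and
    characterising its splicing landscape. Classifies reads into
    full-length non-chimeric (FLnc) versus non-full-length by primer and
    poly(A) detection, collapses aligned full-length isoforms into
    transcript loci by intron-chain identity while ignoring 5' end
    differences, validates splice-junction motifs against short-read
    junction counts, classifies alternative-splicing events into the five
    major types (intron retention, exon skipping, alternative acceptor,
    alternative donor, mutually exclusive exons), calls poly(A) cleavage
    sites from FLnc 3' ends with internal-priming filtering and
    poly(A)-signal motif discovery, estimates percent-spliced-in with
    Beta posteriors and Bayes-factor differential calls, and annotates
    ORFs and long non-coding RNA candidates. Ships a synthetic-data
    generator that plants known gene structures, splicing events and
    cleavage sites so every stage can be tested against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    igraph,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
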