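Package: hatscreen
Title: Directed-Evolution Screen Analysis and Integration-Site Profiling
    for hAT-Family Transposases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing directed-evolution screens of hAT-family
    DNA transposases such as TcBuster. Implements candidate-substitution
    discovery from protein multiple alignments (conserved residues the
    target sequence lacks), long-read genotyping of shuffled
    combinatorial mutant libraries against a designed-mutation catalogue
    with library-diversity statistics, per-mutation weighted enrichment
    scoring (WES = ln(E) x sqrt(mutant read counts)) between naive and
    sorted cell populations, and transposon integration-site recovery
    from ITR-genome junction reads with target-site-duplication
    reconciliation, distance-to-TSS and genomic-context safety metrics
    against a uniform-random baseline. A synthetic-data module generates
    every pipeline input with known ground truth for closed-loop
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    withr,
    Rcpp,
    methods,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    seqinr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
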