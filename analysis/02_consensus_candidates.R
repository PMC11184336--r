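#!/usr/bin/env Rscript
# Candidate hyperactive substitutions from the family alignment:
# conserved residues the target transposase lacks, checked against the
# positions planted by the generator.

suppressMessages(library(hatscreen))

outdir <- "results"
msa <- read_msa_fasta("results/data/family_msa.fasta")
planted <- read_tsv("results/data/planted_candidates.tsv")

cand <- candidate_substitutions(msa, "target",
                                min_conservation = 0.6, min_coverage = 0.5)
write_tsv(cand, file.path(outdir, "candidate_substitutions.tsv"))

hits <- intersect(cand$label, planted$label)
cat("candidates found:", nrow(cand), "\n")
cat("planted positions recovered:", length(hits), "of", nrow(planted),
    sprintf("(precision %.2f, recall %.2f)\n",
            length(hits) / max(1, nrow(cand)),
            length(hits) / max(1, nrow(planted))))
cat("labels:", paste(cand$label, collapse = ", "), "\n")
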