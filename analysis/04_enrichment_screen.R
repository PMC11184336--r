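#!/usr/bin/env Rscript
# Per-mutation weighted enrichment between the naive and sorted
# populations, and recovery of the planted hyperactive mutations.

suppressMessages(library(hatscreen))

outdir <- "results"
ref <- as.character(Biostrings::readDNAStringSet("results/data/reference.fasta"))[[1]]
design <- load_design("results/data/design.tsv", ref)
truth <- read_tsv("results/data/true_effects.tsv")

cn <- mutation_counts(genotype_reads(read_reads("results/data/naive.fastq"),
                                     design, ref))
cs <- mutation_counts(genotype_reads(read_reads("results/data/sorted.fastq"),
                                     design, ref))
et <- enrichment_table(cn, cs, design, pseudocount = 0.5)
write_tsv(as.data.frame(et), file.path(outdir, "enrichment.tsv"))

cat("top 10 mutations by weighted enrichment score:\n")
print(head(as.data.frame(et)[, c("rank", "label", "reads_mut_naive",
                                 "reads_mut_sort", "E", "WES")], 10),
      row.names = FALSE)

top20 <- et$mutation_id[1:20]
cat("\nplanted positives in WES top 20:", sum(truth$mutation_id %in% top20),
    "of", nrow(truth), "\n")
tvec <- setNames(rep(0, nrow(design)), design$mutation_id)
tvec[truth$mutation_id] <- truth$effect
cat(sprintf("Spearman rho (binary truth vs WES): %.3f\n",
            cor(tvec[et$mutation_id], et$WES, method = "spearman")))
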