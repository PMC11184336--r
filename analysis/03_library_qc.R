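#!/usr/bin/env Rscript
# Genotype the naive-population long reads against the designed-mutation
# catalogue and summarise library diversity, plus the combinatorial size
# of the design space.

suppressMessages(library(hatscreen))

outdir <- "results"
ref <- as.character(Biostrings::readDNAStringSet("results/data/reference.fasta"))[[1]]
design <- load_design("results/data/design.tsv", ref)
reads <- read_reads("results/data/naive.fastq")

calls <- genotype_reads(reads, design, ref)
stats <- library_stats(calls)
print(stats)

write_tsv(stats$variant_table, file.path(outdir, "naive_variants.tsv"))
write_tsv(stats$per_mutation, file.path(outdir, "naive_mutation_counts.tsv"))
write_json(list(total_reads = stats$total_reads,
                passing_reads = stats$passing_reads,
                n_unique_variants = stats$n_unique_variants,
                mean_mutation_load = signif(stats$mean_mutation_load, 6)),
           file.path(outdir, "library_stats.json"))

cs <- combinatorial_space(nrow(design), 4)
cat("design space, 1..4 of", nrow(design), "mutations:", cs$count,
    "variants\n")
cat("design space, all combinations:",
    combinatorial_space(nrow(design), "all")$count, "\n")
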