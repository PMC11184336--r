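#!/usr/bin/env Rscript
# Generate every input for the downstream analyses with known ground
# truth: a transposase-scale reference CDS, a 108-substitution design,
# a shuffled variant library read out as naive vs sorted populations
# (10 planted hyperactive mutations), and an annotated 2-Mb toy genome
# with 500 transposon insertions read out as ITR-genome junction reads.

suppressMessages(library(hatscreen))

seed <- 2026L
outdir <- "results/data"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

ref <- make_reference(686, seed = seed)
design <- make_design(ref, 108, seed = seed)
write_fasta(setNames(ref$cds, "reference"), file.path(outdir, "reference.fasta"))
write_design_tsv(design, file.path(outdir, "design.tsv"))
cat("reference:", nchar(ref$cds), "nt CDS /", nchar(ref$protein), "aa;",
    nrow(design), "designed substitutions\n")

cfg <- sim_config(seed = seed, n_variants = 10000, mean_mutation_load = 4.4,
                  n_reads_naive = 100000, n_reads_sorted = 100000,
                  read_error_rate = 0.005, selection_stringency = 1)
lib <- simulate_library(design, cfg, n_reads = 0)
cat("library:", length(lib$genotypes), "variants, realized mean load",
    round(mean(lengths(lib$genotypes)), 2), "\n")

positives <- withr::with_seed(derive_seed(seed, "effects"),
                              sort(sample(design$mutation_id, 10)))
effects <- setNames(rep(1, 10), positives)
srt <- simulate_sort(lib, effects, cfg)
write_fastq(srt$naive, file.path(outdir, "naive.fastq"))
write_fastq(srt$sorted, file.path(outdir, "sorted.fastq"))
write_tsv(data.frame(mutation_id = positives, effect = 1),
          file.path(outdir, "true_effects.tsv"))
cat("screen: ", length(srt$naive), "naive +", length(srt$sorted),
    "sorted reads;", length(positives), "mutations carry effect +1\n")

gen <- simulate_genome_and_insertions(cfg, genome_length = 2e6,
                                      n_transcripts = 60,
                                      transcript_fraction = 0.30,
                                      n_insertions = 500)
write_fasta(gen$genome, file.path(outdir, "genome.fasta"))
write_annotation_gff3(gen$annotation, file.path(outdir, "annotation.gff3"))
write_fastq(gen$reads, file.path(outdir, "junctions.fastq"))
write_tsv(gen$sites, file.path(outdir, "true_sites.tsv"))
cat("genome: 2 Mb,", length(gen$annotation$models), "gene models,",
    nrow(gen$sites), "insertions,", length(gen$reads), "junction reads\n")

msa <- simulate_msa(15, 6, conservation = 0.9, seed = seed, length = 300)
Biostrings::writeXStringSet(Biostrings::AAStringSet(msa$msa),
                            file.path(outdir, "family_msa.fasta"))
write_tsv(msa$planted, file.path(outdir, "planted_candidates.tsv"))
cat("MSA: 15 rows x 300 columns,", nrow(msa$planted),
    "planted candidate positions\n")
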