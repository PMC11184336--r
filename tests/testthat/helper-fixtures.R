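# Shared small fixtures and independent oracles, built in code at load.

fix_ref <- make_reference(60, seed = 11)
fix_design <- make_design(fix_ref, 12, seed = 11)

small_cfg <- function(seed = 11, n_variants = 100, n_reads_naive = 1500,
                      n_reads_sorted = 1500, read_error_rate = 0,
                      mean_mutation_load = 3, ...) {
  sim_config(seed = seed, n_variants = n_variants,
             n_reads_naive = n_reads_naive, n_reads_sorted = n_reads_sorted,
             read_error_rate = read_error_rate,
             mean_mutation_load = mean_mutation_load, ...)
}

# Independent per-read re-scan of designed codons using base substr();
# deliberately shares no code with the package's genotyping path.
oracle_states <- function(reads, design) {
  out <- matrix("OTHER", nrow = length(reads), ncol = nrow(design),
                dimnames = list(NULL, design$mutation_id))
  for (k in seq_len(nrow(design))) {
    s <- 3 * design$aa_pos_1based[k] - 2
    cod <- substr(reads, s, s + 2)
    out[cod == design$wt_codon[k], k] <- "WT"
    out[cod == design$mut_codon[k], k] <- "MUT"
  }
  out
}

oracle_counts <- function(reads, design) {
  st <- oracle_states(reads, design)
  data.frame(mutation_id = design$mutation_id,
             mut = as.integer(colSums(st == "MUT")),
             wt = as.integer(colSums(st == "WT")),
             other = as.integer(colSums(st == "OTHER")),
             stringsAsFactors = FALSE)
}

# annotated transcript bp fraction of a simulated genome
transcript_bp_fraction <- function(gen) {
  tx <- gen$annotation$transcripts
  sum(BiocGenerics::width(GenomicRanges::reduce(tx, ignore.strand = TRUE))) /
    nchar(gen$genome[[1]])
}
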