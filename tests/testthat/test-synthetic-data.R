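# Generators: reference, design, library, sort, MOI, genome/insertions, MSA.

test_that("make_reference obeys the length contract and is deterministic", {
  r <- make_reference(10, seed = 1)
  expect_equal(nchar(r$cds), 33)  # 3 * 10 codons + stop
  expect_equal(nchar(r$protein), 10)
  expect_identical(make_reference(10, seed = 1), r)
  expect_false(identical(make_reference(10, seed = 2)$cds, r$cds))
  expect_error(make_reference(9), "length_aa")
})

test_that("a transposase-scale reference translates cleanly (independent codon table)", {
  skip_if_not_installed("seqinr")
  r <- make_reference(686, seed = 7)
  expect_equal(nchar(r$protein), 686)
  expect_false(grepl("\\*", r$protein))
  aa <- seqinr::translate(seqinr::s2c(r$cds))
  expect_identical(paste(aa[1:686], collapse = ""), r$protein)
  expect_identical(aa[687], "*")
})

test_that("make_design yields distinct positions with real amino-acid changes", {
  r <- make_reference(686, seed = 7)
  d <- make_design(r, 108, seed = 3)
  expect_equal(nrow(d), 108)
  expect_equal(length(unique(d$aa_pos_1based)), 108)
  expect_true(all(d$wt_aa != d$mut_aa))
  # wt codons cross-check against the reference CDS
  cods <- substring(r$cds, 3 * d$aa_pos_1based - 2, 3 * d$aa_pos_1based)
  expect_identical(cods, d$wt_codon)
  # mut codons translate to the stated mutant amino acid
  gc <- Biostrings::GENETIC_CODE
  expect_identical(unname(gc[d$mut_codon]), d$mut_aa)
  expect_equal(nrow(make_design(r, 0)), 0)
  expect_error(make_design(make_reference(12), 20), "exceeds")
})

test_that("error-free library reads differ from the reference only at their mutations", {
  cfg <- small_cfg()
  lib <- simulate_library(fix_design, cfg, n_reads = 50)
  ref <- fix_ref$cds
  for (i in seq_len(20)) {
    v <- lib$read_variant[i]
    expect_identical(lib$reads[[i]], lib$variant_seqs[v])
    st <- oracle_states(lib$reads[i], fix_design)[1, ]
    expect_setequal(names(st)[st == "MUT"], lib$genotypes[[v]])
    expect_true(all(st[setdiff(names(st), lib$genotypes[[v]])] == "WT"))
  }
})

test_that("mutation loads follow the configured zero-truncated Poisson mean", {
  r <- make_reference(200, seed = 2)
  d <- make_design(r, 108, seed = 2)
  cfg <- sim_config(seed = 5, n_variants = 10000, mean_mutation_load = 4.4,
                    n_reads_naive = 0, n_reads_sorted = 0)
  lib <- simulate_library(d, cfg, n_reads = 0)
  loads <- lengths(lib$genotypes)
  expect_true(all(loads >= 1))
  se <- sd(loads) / sqrt(length(loads))
  expect_lt(abs(mean(loads) - 4.4), 3 * se)
})

test_that("zero reads produce a valid empty FASTQ", {
  cfg <- small_cfg()
  lib <- simulate_library(fix_design, cfg, n_reads = 0)
  expect_length(lib$reads, 0)
  p <- tempfile(fileext = ".fastq")
  write_fastq(lib$reads, p)
  expect_true(file.exists(p))
  expect_equal(file.size(p), 0)
  expect_length(read_reads(p), 0)
})

test_that("read conservation: generators emit exactly the requested read counts", {
  cfg <- small_cfg(n_reads_naive = 321, n_reads_sorted = 123)
  lib <- simulate_library(fix_design, cfg, n_reads = 77)
  expect_length(lib$reads, 77)
  srt <- simulate_sort(lib, c(m001 = 0), cfg)
  expect_length(srt$naive, 321)
  expect_length(srt$sorted, 123)
})

test_that("null selection leaves naive and sorted frequencies equal within noise", {
  cfg <- small_cfg(seed = 21, n_reads_naive = 4000, n_reads_sorted = 4000)
  lib <- simulate_library(fix_design, cfg)
  srt <- simulate_sort(lib, setNames(numeric(0), character(0)), cfg)
  expect_true(all(srt$weights == 1))
  cn <- oracle_counts(srt$naive, fix_design)
  cs <- oracle_counts(srt$sorted, fix_design)
  Fn <- cn$mut / (cn$mut + cn$wt); Fs <- cs$mut / (cs$mut + cs$wt)
  se <- sqrt(Fn * (1 - Fn) / (cn$mut + cn$wt) + Fs * (1 - Fs) / (cs$mut + cs$wt))
  expect_true(all(abs(Fs - Fn) < 4 * se + 1e-12))
})

test_that("a beneficial mutation is enriched in nearly all replicates", {
  r <- make_reference(30, seed = 4)
  d <- make_design(r, 5, seed = 4)
  hits <- 0
  for (s in 1:100) {
    cfg <- sim_config(seed = 1000 + s, n_variants = 60, n_reads_naive = 400,
                      n_reads_sorted = 400, read_error_rate = 0,
                      mean_mutation_load = 2, selection_stringency = 1)
    lib <- simulate_library(d, cfg)
    srt <- simulate_sort(lib, c(m002 = 2), cfg)
    cn <- oracle_counts(srt$naive, d); cs <- oracle_counts(srt$sorted, d)
    Fn <- cn$mut[2] / (cn$mut[2] + cn$wt[2])
    Fs <- cs$mut[2] / (cs$mut[2] + cs$wt[2])
    if (Fs > Fn) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("MOI copy-number distribution matches the Poisson law", {
  expect_equal(unname(moi_copy_distribution(0)["p0"]), 1)
  p <- moi_copy_distribution(0.3)
  expect_equal(unname(p["p0"]), exp(-0.3), tolerance = 1e-12)
  expect_equal(unname(p["p1"]), 0.3 * exp(-0.3), tolerance = 1e-12)
  expect_equal(unname(p["p0"] + p["p1"]), 0.9631, tolerance = 1e-4)
  for (m in c(0.1, 0.3, 1, 5)) expect_equal(sum(moi_copy_distribution(m)), 1)
  expect_error(moi_copy_distribution(-1), "moi")
})

test_that("simulated junction reads carry the TSD adjacent to the junction", {
  cfg <- sim_config(seed = 8, tsd_length = 8)
  gen <- simulate_genome_and_insertions(cfg, genome_length = 60000,
                                        n_transcripts = 4, n_insertions = 15,
                                        reads_per_junction = 1)
  expect_equal(nrow(gen$sites), 15)
  expect_true(all(nchar(gen$sites$tsd) == 8))
  probe <- cfg$itr_probe
  for (j in seq_len(nrow(gen$sites))) {
    rr <- gen$reads[[sprintf("site%04d_right_1", j)]]
    rl <- gen$reads[[sprintf("site%04d_left_1", j)]]
    # strip the (possibly truncated) probe anchor
    fr <- sub(paste0("^.*?", substr(probe, nchar(probe) - 11, nchar(probe))),
              "", rr, perl = TRUE)
    fl <- sub(paste0("^.*?", substr(probe, nchar(probe) - 11, nchar(probe))),
              "", rl, perl = TRUE)
    expect_identical(substr(fr, 1, 8), gen$sites$tsd[j])
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fl)))
    expect_identical(substr(rc, nchar(rc) - 7, nchar(rc)), gen$sites$tsd[j])
  }
})

test_that("zero insertions give empty reads and site list; overfull request errors", {
  cfg <- sim_config(seed = 8)
  gen <- simulate_genome_and_insertions(cfg, genome_length = 30000,
                                        n_transcripts = 2, n_insertions = 0)
  expect_equal(nrow(gen$sites), 0)
  expect_length(gen$reads, 0)
  expect_error(
    simulate_genome_and_insertions(cfg, genome_length = 2000,
                                   n_transcripts = 2, n_insertions = 5000),
    "exceeds")
})

test_that("uniform insertions land in transcripts at the annotated bp fraction", {
  cfg <- sim_config(seed = 17)
  gen <- simulate_genome_and_insertions(cfg, genome_length = 5e5,
                                        n_transcripts = 20, n_insertions = 1000,
                                        reads_per_junction = 0)
  frac_tx <- transcript_bp_fraction(gen)
  cls <- classify_context(gen$sites, gen$annotation)
  p_hat <- mean(cls != "outside_transcript")
  half <- 2.576 * sqrt(frac_tx * (1 - frac_tx) / 1000)
  expect_lt(abs(p_hat - frac_tx), half)
})

test_that("generators are byte-identical under one seed", {
  cfg <- small_cfg(seed = 33)
  a <- simulate_library(fix_design, cfg, n_reads = 40)
  b <- simulate_library(fix_design, cfg, n_reads = 40)
  expect_identical(a$reads, b$reads)
  expect_identical(a$genotypes, b$genotypes)
  g1 <- simulate_genome_and_insertions(cfg, genome_length = 40000,
                                       n_transcripts = 3, n_insertions = 10)
  g2 <- simulate_genome_and_insertions(cfg, genome_length = 40000,
                                       n_transcripts = 3, n_insertions = 10)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$reads, g2$reads)
  expect_identical(g1$sites, g2$sites)
  m1 <- simulate_msa(8, 3, 0.9, seed = 5)
  m2 <- simulate_msa(8, 3, 0.9, seed = 5)
  expect_identical(m1$msa, m2$msa)
})

test_that("simulate_msa plants recoverable candidates", {
  sm <- simulate_msa(10, 2, conservation = 1.0, seed = 2)
  cand <- candidate_substitutions(sm$msa, "target", min_conservation = 0.9)
  expect_setequal(cand$label, sm$planted$label)  # precision = recall = 1
  sm0 <- simulate_msa(10, 0, conservation = 1.0, seed = 2)
  expect_equal(nrow(candidate_substitutions(sm0$msa, "target")), 0)
  expect_error(simulate_msa(10, 500, 0.9, length = 100), "exceeds")
  expect_error(simulate_msa(1, 2, 0.9), "n_seqs")
})
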