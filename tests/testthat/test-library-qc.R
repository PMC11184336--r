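# Genotyping long reads against the designed-mutation catalogue and
# library-diversity statistics.

test_that("design tables round-trip and are validated against the reference", {
  p <- tempfile(fileext = ".tsv")
  write_design_tsv(fix_design, p)
  d2 <- load_design(p, fix_ref)
  expect_equal(nrow(d2), nrow(fix_design))
  expect_identical(d2$mut_codon, fix_design$mut_codon)

  df <- read_tsv(p)
  df$wt_codon[3] <- setdiff(c("AAA", "CCC", "GGG"), df$wt_codon[3])[1]
  bad <- tempfile(fileext = ".tsv"); write_tsv(df, bad)
  expect_error(load_design(bad, fix_ref), df$mutation_id[3])

  df2 <- read_tsv(p); df2$mutation_id[2] <- df2$mutation_id[1]
  dup <- tempfile(fileext = ".tsv"); write_tsv(df2, dup)
  expect_error(load_design(dup, fix_ref), "duplicate")
})

test_that("full-length filter accepts exact, rejects partial, detects RC", {
  ref <- fix_ref$cds
  r1 <- filter_full_length(ref, ref)
  expect_true(r1$accepted); expect_equal(r1$identity, 1)
  half <- substr(ref, 1, nchar(ref) %/% 2)
  r2 <- filter_full_length(half, ref, min_coverage = 0.95)
  expect_false(r2$accepted)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(ref)))
  r3 <- filter_full_length(rc, ref)
  expect_true(r3$accepted); expect_identical(r3$orientation, "rc")
  expect_identical(r3$projected, ref)
  expect_error(filter_full_length("ACGU", ref), "non-DNA")
})

test_that("filter pass-rate is monotone non-increasing in both thresholds", {
  cfg <- small_cfg(seed = 41, read_error_rate = 0.04)
  lib <- simulate_library(fix_design, cfg, n_reads = 400)
  rate <- function(mi, mc) mean(filter_reads(lib$reads, fix_ref$cds,
                                             min_coverage = mc,
                                             min_identity = mi)$accepted)
  ids <- c(0.8, 0.9, 0.95, 0.99)
  rates <- vapply(ids, rate, numeric(1), mc = 0.95)
  expect_true(all(diff(rates) <= 0))
})

test_that("deletions route through the alignment path and disrupt codons to OTHER", {
  ref <- fix_ref$cds
  pos <- fix_design$aa_pos_1based[2]
  s <- 3 * pos - 2
  # delete designed codon 2 outright
  del <- paste0(substr(ref, 1, s - 1), substr(ref, s + 3, nchar(ref)))
  flt <- filter_full_length(del, ref, min_coverage = 0.95, min_identity = 0.85)
  expect_true(flt$accepted)
  expect_equal(nchar(flt$projected), nchar(ref))
  cg <- call_genotype(flt, fix_design)
  expect_identical(unname(cg$states[2]), "OTHER")
})

test_that("genotypes are called exactly on constructed reads", {
  ref <- fix_ref$cds
  ids <- fix_design$mutation_id[c(1, 4)]
  read <- ref
  for (k in c(1, 4)) {
    s <- 3 * fix_design$aa_pos_1based[k] - 2
    substr(read, s, s + 2) <- fix_design$mut_codon[k]
  }
  cg <- call_genotype(filter_full_length(read, ref), fix_design)
  expect_setequal(cg$genotype, ids)
  # wild-type read: empty genotype
  cg0 <- call_genotype(filter_full_length(ref, ref), fix_design)
  expect_length(cg0$genotype, 0)
  expect_true(all(cg0$states == "WT"))
})

test_that("a non-designed codon at a designed position counts as OTHER, not wt or mut", {
  ref <- fix_ref$cds
  k <- 3
  s <- 3 * fix_design$aa_pos_1based[k] - 2
  third <- setdiff(c("AAA", "CCC", "GGG", "TTT"),
                   c(fix_design$wt_codon[k], fix_design$mut_codon[k]))[1]
  read <- ref; substr(read, s, s + 2) <- third
  calls <- genotype_reads(c(r1 = read), fix_design)
  cnt <- mutation_counts(calls)
  expect_equal(cnt$mut[k], 0)
  expect_equal(cnt$wt[k], 0)
  expect_equal(cnt$other[k], 1)
  expect_equal(sum(cnt$wt[-k]), nrow(fix_design) - 1)
})

test_that("library stats average mutation load over unique variants, not reads", {
  keys <- c("m001", "m001", "m001,m002", "m003,m004,m005")
  st <- library_stats(keys)
  expect_equal(st$n_unique_variants, 3)
  expect_equal(st$mean_mutation_load, 2)  # (1 + 2 + 3) / 3
  # duplicates increment support only
  expect_equal(st$variant_table$support[st$variant_table$genotype == "m001"], 2)
  st0 <- library_stats(character(0))
  expect_equal(st0$n_unique_variants, 0)
  expect_equal(st0$mean_mutation_load, 0)
})

test_that("estimated mean load matches the generator on error-free reads", {
  r <- make_reference(200, seed = 6)
  d <- make_design(r, 40, seed = 6)
  cfg <- sim_config(seed = 14, n_variants = 800, read_error_rate = 0,
                    mean_mutation_load = 4.4)
  lib <- simulate_library(d, cfg, n_reads = 4000)
  stats <- library_stats(genotype_reads(lib$reads, d))
  loads <- stats$variant_table$load
  se <- sd(loads) / sqrt(length(loads))
  expect_lt(abs(stats$mean_mutation_load - 4.4), 3 * se)
})

test_that("pipeline counts equal a naive per-read re-scan (oracle equivalence)", {
  cfg <- small_cfg(seed = 51, read_error_rate = 0.01)
  lib <- simulate_library(fix_design, cfg, n_reads = 1200)
  calls <- genotype_reads(lib$reads, fix_design)
  # error rate is low enough that every read passes, so the oracle sees
  # the same read set
  expect_equal(calls$n_pass, calls$n_total)
  expect_equal(mutation_counts(calls), oracle_counts(lib$reads, fix_design))
})

test_that("combinatorial space is exact: examples and brute-force oracle", {
  expect_equal(combinatorial_space(3, 2)$approx, 6)
  cs4 <- combinatorial_space(108, 4)
  expect_identical(cs4$count, "5569137")
  expect_equal(cs4$approx, sum(choose(108, 1:4)))  # independent evaluation
  all108 <- combinatorial_space(108, "all")
  expect_equal(all108$approx, 2^108 - 1, tolerance = 1e-12)
  expect_equal(nchar(all108$count), 33)  # ~3.25e32
  # subset-enumeration oracle for small n
  for (n in 1:12) {
    enum <- sum(vapply(1:n, function(k) ncol(utils::combn(n, k)), numeric(1)))
    expect_equal(combinatorial_space(n, "all")$approx, enum)
    expect_equal(combinatorial_space(n, "all")$approx, 2^n - 1)
  }
  for (n in 13:20)
    expect_equal(combinatorial_space(n, "all")$approx, 2^n - 1)
  expect_error(combinatorial_space(-1, 2), "n_mutations")
  expect_error(combinatorial_space(10, 11), "max_load")
})
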