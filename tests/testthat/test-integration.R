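# Junction extraction, mapping, site clustering, TSS distances, context
# classes and the profile summary.

PROBE <- sim_config()$itr_probe

test_that("junction extraction trims the probe and applies length gates", {
  g40 <- strrep("ACGT", 10)
  r <- c(j1 = paste0(PROBE, g40))
  jx <- extract_junctions(r, PROBE)
  expect_equal(nrow(jx), 1)
  expect_identical(jx$fragment, g40)
  # read that is transposon over its whole length is discarded
  expect_equal(nrow(extract_junctions(c(v = PROBE), PROBE)), 0)
  # short genomic remainder is discarded
  short <- c(s = paste0(PROBE, "ACGTACGTAC"))
  expect_equal(nrow(extract_junctions(short, PROBE, min_genomic_len = 20)), 0)
  # truncated probe anchor still matches
  trunc <- c(t = paste0(substr(PROBE, 15, nchar(PROBE)), g40))
  expect_equal(nrow(extract_junctions(trunc, PROBE)), 1)
  # reverse-complement junction read is recognised
  rc <- c(r = as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(paste0(PROBE, g40)))))
  jrc <- extract_junctions(rc, PROBE)
  expect_equal(nrow(jrc), 1)
  expect_identical(jrc$orientation, "rc")
  expect_identical(jrc$fragment, g40)
  expect_error(extract_junctions(r, ""), "empty")
})

test_that("fragments map to junction boundaries with strand symmetry", {
  set.seed(4)
  g <- paste(sample(c("A", "C", "G", "T"), 30000, replace = TRUE),
             collapse = "")
  genome <- c(chrT = g)
  frag <- substring(g, 10001, 10040)  # 0-based start 10000
  m <- map_fragments(c(f1 = frag), genome)
  expect_identical(m$status, "mapped")
  expect_identical(m$side, "right")
  expect_equal(m$boundary, 10000)
  # its reverse complement is a left-side junction ending at 10040
  frc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(frag)))
  m2 <- map_fragments(c(f2 = frc), genome)
  expect_identical(m2$side, "left")
  expect_equal(m2$boundary, 10040)
  # a duplicated fragment is a multimapper and is excluded
  gdup <- c(chrT = paste0(g, substring(g, 10001, 10040), strrep("GATC", 25)))
  m3 <- map_fragments(c(f3 = frag), gdup)
  expect_identical(m3$status, "multimap")
  expect_true(is.na(m3$boundary))
  # junk never seen in the genome is unmapped
  m4 <- map_fragments(c(f4 = strrep("AC", 20)), genome)
  expect_identical(m4$status, "unmapped")
})

test_that("clustering merges duplicates and reconciles TSD-offset junction pairs", {
  set.seed(5)
  g <- paste(sample(c("A", "C", "G", "T"), 50000, replace = TRUE),
             collapse = "")
  genome <- c(chrT = g)
  loci <- data.frame(
    fragment_id = c("a", "b", "c", "d", "e"),
    contig = "chrT",
    boundary = c(1000L, 1000L, 1008L, 20000L, 30000L),
    side = c("right", "right", "left", "right", "right"),
    status = "mapped", stringsAsFactors = FALSE)
  sites <- cluster_sites(loci, genome, merge_window = 5, tsd_length = 8)
  expect_equal(nrow(sites), 3)
  s1 <- sites[sites$point == 1000, ]
  expect_equal(s1$support, 3)  # two right + one paired left
  expect_equal(s1$n_sides, 2)
  expect_identical(s1$tsd, substring(g, 1001, 1008))
  expect_equal(nchar(s1$tsd), 8)
  # loci far apart remain distinct single-sided sites
  expect_true(all(c(20000, 30000) %in% sites$point))
})

test_that("TSS distances are strand-aware, nearest-of-any, and order-invariant", {
  tx <- GenomicRanges::GRanges("chrT",
                               IRanges::IRanges(c(1001, 5001), c(2000, 6000)),
                               strand = c("+", "-"))
  ann <- list(transcripts = tx, cds = GenomicRanges::GRanges())
  # plus-strand TSS point = 1000; minus-strand TSS point = 6000
  sites <- data.frame(contig = "chrT", point = c(1000, 1500, 6000, 3500),
                      stringsAsFactors = FALSE)
  d <- distance_to_tss(sites, ann)
  expect_equal(d, c(0, 500, 0, 2500))
  # nearest of several: 300 beats 1000
  s2 <- data.frame(contig = "chrT", point = 1300, stringsAsFactors = FALSE)
  ann2 <- list(transcripts = GenomicRanges::GRanges(
    "chrT", IRanges::IRanges(c(301, 1601), c(500, 1800)), strand = "+"))
  expect_equal(distance_to_tss(s2, ann2), 300)
  # record order does not matter
  ann_rev <- list(transcripts = rev(tx), cds = GenomicRanges::GRanges())
  expect_equal(distance_to_tss(sites, ann_rev), d)
  # unknown contig: NA with a warning
  s3 <- data.frame(contig = "chrZ", point = 1, stringsAsFactors = FALSE)
  expect_warning(d3 <- distance_to_tss(s3, ann), "absent")
  expect_true(is.na(d3))
})

test_that("context classification follows coding > noncoding > outside precedence", {
  tx <- GenomicRanges::GRanges("chrT", IRanges::IRanges(1001, 5000),
                               strand = "+")
  cds <- GenomicRanges::GRanges("chrT", IRanges::IRanges(1201, 1400),
                                strand = "+")
  ann <- list(transcripts = tx, cds = cds)
  sites <- data.frame(contig = "chrT", point = c(1250, 2000, 8000),
                      stringsAsFactors = FALSE)
  expect_identical(classify_context(sites, ann),
                   c("coding_exon", "transcript_noncoding",
                     "outside_transcript"))
})

test_that("profile summary handles edge cases", {
  cfg <- sim_config(seed = 23)
  gen <- simulate_genome_and_insertions(cfg, genome_length = 50000,
                                        n_transcripts = 4, n_insertions = 10,
                                        reads_per_junction = 0)
  tsspts <- annotation_tss(gen$annotation)
  sites <- data.frame(contig = tsspts$contig, point = tsspts$point,
                      stringsAsFactors = FALSE)
  prof <- profile_summary(sites, gen$annotation, gen$genome,
                          n_random = 500, n_bootstrap = 0, seed = 1)
  expect_equal(prof$median_tss_distance, 0)  # every site at a TSS
  expect_true(is.na(prof$median_tss_se))     # no bootstrap requested
  expect_equal(sum(prof$fractions), 1, tolerance = 1e-9)
  expect_error(profile_summary(gen$sites[0, ], gen$annotation, gen$genome),
               "empty")
})

test_that("closed loop: planted insertions recovered with exact TSDs", {
  cfg <- sim_config(seed = 61)
  gen <- simulate_genome_and_insertions(cfg, genome_length = 3e5,
                                        n_transcripts = 12, n_insertions = 80)
  jx <- extract_junctions(gen$reads, cfg$itr_probe)
  loci <- map_fragments(jx, gen$genome)
  sites <- cluster_sites(loci, gen$genome, merge_window = 5,
                         tsd_length = cfg$tsd_length)
  recall <- mean(gen$sites$point %in% sites$point)
  expect_gte(recall, 0.95)
  m <- match(sites$point, gen$sites$point)
  hit <- !is.na(m)
  expect_identical(sites$tsd[hit], gen$sites$tsd[m[hit]])
})

test_that("strand symmetry: a reverse-complemented genome mirrors the sites", {
  cfg <- sim_config(seed = 71)
  gen <- simulate_genome_and_insertions(cfg, genome_length = 1e5,
                                        n_transcripts = 5, n_insertions = 25)
  jx <- extract_junctions(gen$reads, cfg$itr_probe)
  L <- nchar(gen$genome[[1]])
  t <- cfg$tsd_length
  fwd <- cluster_sites(map_fragments(jx, gen$genome), gen$genome, 5, t)
  grc <- setNames(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(gen$genome[[1]]))), names(gen$genome))
  rev <- cluster_sites(map_fragments(jx, grc), grc, 5, t)
  # an insertion spanning [p, p+t) maps to [L - p - t, L - p) on the rc
  expect_setequal(rev$point, L - fwd$point - t)
  expect_setequal(rev$tsd,
                  as.character(Biostrings::reverseComplement(
                    Biostrings::DNAStringSet(fwd$tsd))))
})

test_that("uniform-random baseline converges to the annotated transcript fraction", {
  cfg <- sim_config(seed = 81)
  gen <- simulate_genome_and_insertions(cfg, genome_length = 4e5,
                                        n_transcripts = 16, n_insertions = 50,
                                        reads_per_junction = 0)
  frac_tx <- transcript_bp_fraction(gen)
  prof <- profile_summary(gen$sites, gen$annotation, gen$genome,
                          n_random = 10000, n_bootstrap = 0, seed = 2)
  base_in_tx <- 1 - prof$baseline$fractions[["outside_transcript"]]
  half <- 3 * sqrt(frac_tx * (1 - frac_tx) / 10000)
  expect_lt(abs(base_in_tx - frac_tx), half + 0.005)
})

test_that("pre-mapped loci import matches the internal mapper", {
  set.seed(6)
  g <- paste(sample(c("A", "C", "G", "T"), 40000, replace = TRUE),
             collapse = "")
  genome <- c(chrT = g)
  frag <- substring(g, 5001, 5040)
  frc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(frag)))
  internal <- map_fragments(c(a = frag, b = frc), genome)
  tsv <- tempfile(fileext = ".tsv")
  write_tsv(data.frame(contig = "chrT", pos_1based = c(5001, 5001),
                       strand = c("+", "-"), fragment_id = c("a", "b"),
                       width = c(40, 40), stringsAsFactors = FALSE), tsv)
  imported <- read_mapped_loci(tsv)
  expect_equal(imported$boundary, internal$boundary)
  expect_identical(imported$side, internal$side)
})
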