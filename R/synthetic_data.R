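# Synthetic-data generators: every input the screen pipeline consumes,
# with ground truth returned alongside. Defaults reproduce the study
# conditions of the screen being modelled: 108 designed codon
# substitutions shuffled into a variant library with a mean realized
# mutation load of 4.4, naive vs sorted populations read out by
# high-accuracy long reads, and ITR-genome junction reads from
# transposon insertions carrying an 8-bp target-site duplication.

#' Simulation configuration
#'
#' Collects the knobs shared by the generators. Identical seeds yield
#' byte-identical outputs from every generator.
#'
#' @param seed master seed; per-stage streams are derived from it via
#'   [derive_seed()].
#' @param read_error_rate per-base substitution error probability of the
#'   simulated long reads (default 0.005, CCS-like).
#' @param mean_mutation_load mean number of designed mutations per
#'   variant (zero-truncated Poisson mean, must exceed 1; default 4.4).
#' @param n_variants number of library variants.
#' @param n_reads_naive,n_reads_sorted reads drawn from the naive and
#'   sorted populations.
#' @param selection_stringency scale applied to summed per-mutation
#'   activity effects before exponentiation into sampling weights.
#' @param tsd_length target-site duplication length in bases (8 for
#'   hAT-family elements).
#' @param itr_probe transposon-terminal sequence used as the junction
#'   anchor in simulated junction reads.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       read_error_rate = 0.005,
                       mean_mutation_load = 4.4,
                       n_variants = 10000L,
                       n_reads_naive = 200000L,
                       n_reads_sorted = 200000L,
                       selection_stringency = 1,
                       tsd_length = 8L,
                       itr_probe = "CAGTGACAATGTGCCCTATCAGTGATAGAG") {
  assert_prob(read_error_rate, "read_error_rate")
  if (!is.numeric(mean_mutation_load) || mean_mutation_load <= 1)
    stop("'mean_mutation_load' must exceed 1 (zero-truncated Poisson mean)")
  if (!is.numeric(selection_stringency) || selection_stringency < 0)
    stop("'selection_stringency' must be >= 0")
  assert_dna(itr_probe, "itr_probe")
  cfg <- list(seed = assert_count(seed, "seed"),
              read_error_rate = read_error_rate,
              mean_mutation_load = mean_mutation_load,
              n_variants = assert_count(n_variants, "n_variants"),
              n_reads_naive = assert_count(n_reads_naive, "n_reads_naive"),
              n_reads_sorted = assert_count(n_reads_sorted, "n_reads_sorted"),
              selection_stringency = selection_stringency,
              tsd_length = assert_count(tsd_length, "tsd_length", min = 1),
              itr_probe = toupper(itr_probe))
  structure(cfg, class = "sim_config")
}

#' Generate a reference transposase CDS
#'
#' Random codons with no internal stop, an ATG start, and one terminal
#' stop codon, so the CDS is `3 * length_aa + 3` nt.
#'
#' @param length_aa protein length in residues (>= 10).
#' @param seed integer seed.
#' @return list with `cds` and `protein` (character scalars).
#' @export
make_reference <- function(length_aa, seed = 1L) {
  if (!is.numeric(length_aa) || length_aa < 10)
    stop("'length_aa' must be >= 10")
  length_aa <- as.integer(length_aa)
  ct <- codon_table()
  sense <- ct$codon[ct$aa != "*"]
  stops <- ct$codon[ct$aa == "*"]
  with_seed(derive_seed(seed, "reference"), {
    body <- sample(sense, length_aa - 1L, replace = TRUE)
    cds <- paste(c("ATG", body, sample(stops, 1L)), collapse = "")
  })
  list(cds = cds, protein = substr(translate_cds(cds), 1L, length_aa))
}

#' Design a catalogue of codon substitutions
#'
#' Draws `n_mutations` distinct codon positions (excluding the start and
#' stop codons) and, at each, a mutant codon encoding a different amino
#' acid — at most one designed mutation per codon position.
#'
#' @param reference output of [make_reference()] (or a list with `$cds`).
#' @param n_mutations number of designed substitutions (108 in the
#'   screen modelled here).
#' @param seed integer seed.
#' @return data frame of class `mutation_design` with columns
#'   `mutation_id`, `aa_pos_1based`, `wt_aa`, `mut_aa`, `wt_codon`,
#'   `mut_codon`, `label`; the reference CDS is kept in
#'   `attr(, "reference")`.
#' @export
make_design <- function(reference, n_mutations, seed = 1L) {
  cds <- if (is.list(reference)) reference$cds else reference
  cods <- codons_of(cds)
  n_aa <- length(cods) - 1L  # last codon is the stop
  eligible <- 2:n_aa         # keep the ATG start codon intact
  if (n_mutations > length(eligible))
    stop("'n_mutations' exceeds the number of mutable codon positions (",
         length(eligible), ")")
  ct <- codon_table()
  sense <- ct[ct$aa != "*", ]
  if (n_mutations == 0) {
    out <- data.frame(mutation_id = character(0), aa_pos_1based = integer(0),
                      wt_aa = character(0), mut_aa = character(0),
                      wt_codon = character(0), mut_codon = character(0),
                      label = character(0), stringsAsFactors = FALSE)
    attr(out, "reference") <- cds
    class(out) <- c("mutation_design", "data.frame")
    return(out)
  }
  with_seed(derive_seed(seed, "design"), {
    pos <- sort(sample(eligible, n_mutations))
    wt_codon <- cods[pos]
    wt_aa <- ct$aa[match(wt_codon, ct$codon)]
    mut_codon <- vapply(wt_aa, function(a) {
      sample(sense$codon[sense$aa != a], 1L)
    }, character(1))
  })
  mut_aa <- ct$aa[match(mut_codon, ct$codon)]
  out <- data.frame(
    mutation_id = sprintf("m%03d", seq_len(n_mutations)),
    aa_pos_1based = pos, wt_aa = wt_aa, mut_aa = mut_aa,
    wt_codon = wt_codon, mut_codon = unname(mut_codon),
    label = paste0(wt_aa, pos, mut_aa),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "reference") <- cds
  class(out) <- c("mutation_design", "data.frame")
  out
}

# mean of a zero-truncated Poisson is lambda / (1 - exp(-lambda));
# invert numerically to hit a requested mean load
ztpois_lambda <- function(mean) {
  stopifnot(mean > 1)
  uniroot(function(l) l / (1 - exp(-l)) - mean,
          lower = 1e-9, upper = max(10, 3 * mean), tol = 1e-10)$root
}

rztpois <- function(n, lambda) {
  if (n == 0) return(integer(0))
  u <- runif(n, min = ppois(0, lambda), max = 1)
  qpois(u, lambda)
}

apply_mutations <- function(cds, design, ids) {
  if (length(ids) == 0) return(cds)
  rows <- match(ids, design$mutation_id)
  for (r in rows) {
    s <- 3L * design$aa_pos_1based[r] - 2L
    substr(cds, s, s + 2L) <- design$mut_codon[r]
  }
  cds
}

#' Simulate a shuffled mutant library and its long-read readout
#'
#' Per-variant mutation counts follow a zero-truncated Poisson with mean
#' `config$mean_mutation_load`; each variant carries a uniform random
#' subset of the designed mutations. Reads are full-length copies of a
#' uniformly sampled variant with i.i.d. substitution errors at
#' `config$read_error_rate`.
#'
#' @param design a `mutation_design`.
#' @param config a [sim_config()].
#' @param n_reads number of reads to emit (default
#'   `config$n_reads_naive`).
#' @return list of class `sim_library`: `genotypes` (list of mutation-id
#'   vectors, one per variant), `variant_seqs`, `reads` (named character
#'   vector), `read_variant` (variant index per read), `design`,
#'   `reference`.
#' @export
simulate_library <- function(design, config = sim_config(),
                             n_reads = config$n_reads_naive) {
  stopifnot(inherits(design, "mutation_design"))
  cds <- attr(design, "reference")
  n_mut <- nrow(design)
  with_seed(derive_seed(config$seed, "library"), {
    loads <- rztpois(config$n_variants, ztpois_lambda(config$mean_mutation_load))
    loads <- pmin(loads, n_mut)
    genotypes <- lapply(loads, function(k) sort(sample(design$mutation_id, k)))
    variant_seqs <- vapply(genotypes, function(g) apply_mutations(cds, design, g),
                           character(1))
    reads <- character(0)
    read_variant <- integer(0)
    if (n_reads > 0 && config$n_variants > 0) {
      read_variant <- sample.int(config$n_variants, n_reads, replace = TRUE)
      reads <- sample_reads_cpp(variant_seqs, read_variant,
                                config$read_error_rate)
      names(reads) <- sprintf("lib_read_%06d", seq_len(n_reads))
    }
  })
  structure(list(genotypes = genotypes, variant_seqs = variant_seqs,
                 reads = reads, read_variant = read_variant,
                 design = design, reference = cds, config = config),
            class = "sim_library")
}

#' Simulate the selection screen: naive vs sorted read populations
#'
#' Naive reads sample variants uniformly. Sorted reads sample variant
#' `v` with weight proportional to
#' `exp(selection_stringency * sum(effects[genotype(v)]))`, an additive
#' per-mutation activity model on a log scale.
#'
#' @param lib a [simulate_library()] result.
#' @param effects named numeric vector of per-mutation activity effects;
#'   mutations absent from it get effect 0.
#' @param config a [sim_config()] (defaults to the library's own).
#' @param seed seed for the sort stream (default derived from
#'   `config$seed`).
#' @return list of class `sim_sort` with `naive`, `sorted` (named read
#'   vectors), `naive_variant`, `sorted_variant`, and `weights`.
#' @export
simulate_sort <- function(lib, effects, config = lib$config,
                          seed = derive_seed(config$seed, "sort")) {
  stopifnot(inherits(lib, "sim_library"))
  if (length(lib$genotypes) == 0) stop("empty genotype list")
  eff <- setNames(rep(0, nrow(lib$design)), lib$design$mutation_id)
  if (length(effects)) {
    unknown <- setdiff(names(effects), names(eff))
    if (length(unknown)) stop("effects name unknown mutations: ",
                              paste(unknown, collapse = ", "))
    eff[names(effects)] <- effects
  }
  score <- vapply(lib$genotypes, function(g) sum(eff[g]), numeric(1))
  w <- exp(config$selection_stringency * score)
  with_seed(seed, {
    nv <- length(lib$variant_seqs)
    naive_variant <- sample.int(nv, config$n_reads_naive, replace = TRUE)
    sorted_variant <- sample.int(nv, config$n_reads_sorted, replace = TRUE,
                                 prob = w)
    naive <- sample_reads_cpp(lib$variant_seqs, naive_variant,
                              config$read_error_rate)
    sorted <- sample_reads_cpp(lib$variant_seqs, sorted_variant,
                               config$read_error_rate)
  })
  if (length(naive)) names(naive) <- sprintf("naive_%06d", seq_along(naive))
  if (length(sorted)) names(sorted) <- sprintf("sort_%06d", seq_along(sorted))
  structure(list(naive = naive, sorted = sorted,
                 naive_variant = naive_variant,
                 sorted_variant = sorted_variant, weights = w),
            class = "sim_sort")
}

#' Poisson copy-number distribution at a given MOI
#'
#' Probabilities of a cell carrying 0, 1, or >= 2 integrated copies when
#' copy counts are Poisson with mean `moi`. At MOI 0.3 most cells carry
#' 0 or 1 copies (P = 0.963), the rationale for low-MOI transduction in
#' one-variant-per-cell screens.
#'
#' @param moi multiplicity of infection (>= 0).
#' @return named numeric: `p0`, `p1`, `p2plus` (sums to 1).
#' @export
moi_copy_distribution <- function(moi) {
  if (!is.numeric(moi) || length(moi) != 1 || is.na(moi) || moi < 0)
    stop("'moi' must be a single number >= 0")
  p0 <- dpois(0, moi); p1 <- dpois(1, moi)
  c(p0 = p0, p1 = p1, p2plus = 1 - p0 - p1)
}

#' @importFrom stats dpois
NULL

# ---- genome, annotation, insertions, junction reads ----------------------

# Build non-overlapping gene models on one contig. Each transcript span is
# placed in its own slot of the genome; exons cover about `exon_density`
# of the span and CDS is the exonic region minus short terminal UTRs.
simulate_annotation <- function(genome_length, n_transcripts,
                                transcript_fraction, exon_density = 0.5,
                                contig = "chrS") {
  slot <- genome_length / n_transcripts
  span_target <- transcript_fraction * slot
  tx <- vector("list", n_transcripts)
  for (i in seq_len(n_transcripts)) {
    span <- round(span_target * runif(1, 0.7, 1.3))
    span <- max(span, 600)
    lo <- (i - 1) * slot + 1
    start <- floor(lo + runif(1) * max(1, slot - span - 2))
    end <- start + span - 1
    n_exons <- sample(3:7, 1)
    # alternating exon/intron blocks, exons ~ exon_density of the span;
    # lengths rescaled so the model always fits its slot
    we <- runif(n_exons); wi <- runif(n_exons - 1)
    exon_len <- pmax(20, round(we / sum(we) * span * exon_density))
    intron_len <- pmax(20, round(wi / sum(wi) * span * (1 - exon_density)))
    total <- sum(exon_len) + sum(intron_len)
    if (total > span) {
      sc <- span / total
      exon_len <- pmax(10, floor(exon_len * sc))
      intron_len <- pmax(10, floor(intron_len * sc))
    }
    starts <- integer(n_exons); ends <- integer(n_exons)
    cur <- start
    for (e in seq_len(n_exons)) {
      starts[e] <- cur
      ends[e] <- cur + exon_len[e] - 1
      cur <- ends[e] + if (e < n_exons) intron_len[e] else 0
      cur <- cur + 1
    }
    end <- ends[n_exons]
    strand <- sample(c("+", "-"), 1)
    utr <- min(100L, exon_len[1] - 1L, exon_len[n_exons] - 1L)
    cds_start <- min(starts[1] + utr, ends[1])
    cds_end <- max(ends[n_exons] - utr, starts[n_exons])
    if (cds_end < cds_start) { cds_start <- starts[1]; cds_end <- end }
    tx[[i]] <- list(id = sprintf("tx%03d", i), start = start, end = end,
                    strand = strand, exon_starts = starts, exon_ends = ends,
                    cds_start = cds_start, cds_end = cds_end)
  }
  tx_gr <- GenomicRanges::GRanges(
    contig, IRanges::IRanges(vapply(tx, `[[`, numeric(1), "start"),
                             vapply(tx, `[[`, numeric(1), "end")),
    strand = vapply(tx, `[[`, character(1), "strand"))
  names(tx_gr) <- vapply(tx, `[[`, character(1), "id")
  cds_list <- lapply(tx, function(t) {
    s <- pmax(t$exon_starts, t$cds_start); e <- pmin(t$exon_ends, t$cds_end)
    keep <- s <= e
    if (!any(keep)) return(NULL)
    GenomicRanges::GRanges(contig, IRanges::IRanges(s[keep], e[keep]),
                           strand = t$strand, tx_id = t$id)
  })
  cds_gr <- do.call(c, cds_list[!vapply(cds_list, is.null, logical(1))])
  exon_list <- lapply(tx, function(t)
    GenomicRanges::GRanges(contig, IRanges::IRanges(t$exon_starts, t$exon_ends),
                           strand = t$strand, tx_id = t$id))
  exon_gr <- do.call(c, exon_list)
  list(transcripts = tx_gr, cds = cds_gr, exons = exon_gr, models = tx)
}

#' Simulate a toy annotated genome with transposon insertions
#'
#' Generates a random contig with non-overlapping multi-exon gene models,
#' places insertions (uniformly by default, or biased toward TSSs), and
#' emits ITR-genome junction reads for both sides of every insertion. An
#' insertion at between-base point `p` duplicates the `tsd_length` bases
#' `[p, p + tsd)`: the right-side junction read is
#' `probe + genome[p, ...)` and the left-side read is
#' `probe + revcomp(genome[..., p + tsd))`, so both flanks carry the TSD
#' adjacent to the junction.
#'
#' @param config a [sim_config()] (supplies seed, tsd_length, itr_probe).
#' @param seed seed (default derived from `config$seed`).
#' @param genome_length contig length in bases.
#' @param n_transcripts number of gene models.
#' @param transcript_fraction fraction of the contig covered by
#'   transcripts.
#' @param n_insertions number of insertion sites.
#' @param tss_bias probability that a site is drawn near a TSS instead of
#'   uniformly (0 = uniform).
#' @param reads_per_junction junction reads emitted per side per site.
#' @param read_length genomic flank length per junction read.
#' @param junction_error_rate per-base substitution error rate on
#'   junction reads (default 0).
#' @param contig contig name.
#' @return list of class `sim_genome`: `genome` (named character),
#'   `annotation` (list: transcripts/cds/exons GRanges), `sites`
#'   (data.frame contig, point (0-based between-base), strand, tsd),
#'   `reads` (named character vector of junction reads).
#' @export
simulate_genome_and_insertions <- function(config = sim_config(),
                                           seed = derive_seed(config$seed, "genome"),
                                           genome_length = 2e6,
                                           n_transcripts = 60,
                                           transcript_fraction = 0.30,
                                           n_insertions = 500,
                                           tss_bias = 0,
                                           reads_per_junction = 2,
                                           read_length = 60,
                                           junction_error_rate = 0,
                                           contig = "chrS") {
  tsd <- config$tsd_length
  margin <- read_length + tsd + 1
  if (n_insertions > (genome_length - 2 * margin) / 2)
    stop("insertion count exceeds available positions")
  with_seed(seed, {
    genome <- random_dna(genome_length)
    ann <- simulate_annotation(genome_length, n_transcripts,
                               transcript_fraction, contig = contig)
    pts <- integer(0)
    if (n_insertions > 0) {
      avail <- margin:(genome_length - margin)
      if (tss_bias > 0) {
        tss <- annotation_tss(ann)$point
        near <- as.integer(round(rep(tss, length.out = n_insertions) +
                                   rnorm(n_insertions, 0, 2000)))
        unif <- sample(avail, n_insertions, replace = FALSE)
        use_tss <- runif(n_insertions) < tss_bias
        pts <- ifelse(use_tss, pmin(pmax(near, margin), genome_length - margin),
                      unif)
        pts <- unique(pts)
        while (length(pts) < n_insertions)
          pts <- unique(c(pts, sample(avail, n_insertions - length(pts))))
        pts <- pts[seq_len(n_insertions)]
      } else {
        pts <- sample(avail, n_insertions, replace = FALSE)
      }
      pts <- sort(pts)
    }
    strand <- if (n_insertions > 0) sample(c("+", "-"), n_insertions, TRUE)
              else character(0)
    sites <- data.frame(contig = rep(contig, n_insertions), point = pts,
                        strand = strand,
                        tsd = if (n_insertions > 0)
                          substring(genome, pts + 1, pts + tsd)
                        else character(0),
                        stringsAsFactors = FALSE)
    reads <- character(0)
    if (n_insertions > 0 && reads_per_junction > 0) {
      probe <- config$itr_probe
      plen <- nchar(probe)
      mk <- function(p, side, k) {
        keep <- sample(max(12, plen - 10):plen, 1)  # far-end truncation
        anchor <- substr(probe, plen - keep + 1, plen)
        flank <- if (side == "right") substring(genome, p + 1, p + read_length)
                 else revcomp(substring(genome, p + tsd - read_length + 1, p + tsd))
        paste0(anchor, flank)
      }
      out <- vector("list", n_insertions)
      for (j in seq_len(n_insertions)) {
        rs <- c(vapply(seq_len(reads_per_junction),
                       function(k) mk(pts[j], "right", k), character(1)),
                vapply(seq_len(reads_per_junction),
                       function(k) mk(pts[j], "left", k), character(1)))
        names(rs) <- sprintf("site%04d_%s_%d", j,
                             rep(c("right", "left"), each = reads_per_junction),
                             rep(seq_len(reads_per_junction), 2))
        out[[j]] <- rs
      }
      reads <- unlist(out)
      if (junction_error_rate > 0)
        reads <- setNames(sample_reads_cpp(reads, seq_along(reads),
                                           junction_error_rate), names(reads))
    }
  })
  structure(list(genome = setNames(genome, contig), annotation = ann,
                 sites = sites, reads = reads, config = config),
            class = "sim_genome")
}

#' Write a simulated annotation to GFF3
#'
#' @param ann the `annotation` element of a [simulate_genome_and_insertions()]
#'   result.
#' @param path output GFF3 path.
#' @export
write_annotation_gff3 <- function(ann, path) {
  rows <- list()
  for (t in ann$models) {
    rows[[length(rows) + 1L]] <- data.frame(
      type = "gene", start = t$start, end = t$end, strand = t$strand,
      id = paste0("gene_", t$id), parent = NA_character_)
    rows[[length(rows) + 1L]] <- data.frame(
      type = "mRNA", start = t$start, end = t$end, strand = t$strand,
      id = t$id, parent = paste0("gene_", t$id))
    for (e in seq_along(t$exon_starts)) {
      rows[[length(rows) + 1L]] <- data.frame(
        type = "exon", start = t$exon_starts[e], end = t$exon_ends[e],
        strand = t$strand, id = sprintf("%s_exon%d", t$id, e), parent = t$id)
      cs <- max(t$exon_starts[e], t$cds_start)
      ce <- min(t$exon_ends[e], t$cds_end)
      if (cs <= ce)
        rows[[length(rows) + 1L]] <- data.frame(
          type = "CDS", start = cs, end = ce, strand = t$strand,
          id = sprintf("%s_cds%d", t$id, e), parent = t$id)
    }
  }
  df <- do.call(rbind, rows)
  contig <- as.character(GenomeInfoDb::seqnames(ann$transcripts))[1]
  attrs <- ifelse(is.na(df$parent), paste0("ID=", df$id),
                  paste0("ID=", df$id, ";Parent=", df$parent))
  lines <- c("##gff-version 3",
             paste(contig, "hatscreen", df$type, df$start, df$end, ".",
                   df$strand, ".", attrs, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a protein multiple alignment with planted candidates
#'
#' Builds an alignment of `n_seqs` rows (one row named `target`) in which
#' `n_candidate_positions` planted columns carry a residue in the target
#' that differs from a consensus shared by at least `conservation` of the
#' other rows; everywhere else the target matches the column consensus.
#'
#' @param n_seqs number of rows (>= 2), including the target.
#' @param n_candidate_positions planted candidate columns.
#' @param conservation minimum fraction of non-target rows agreeing on
#'   the consensus residue at planted columns (also the per-column
#'   agreement probability elsewhere).
#' @param seed integer seed.
#' @param length alignment width.
#' @param target_id row name of the target sequence.
#' @return list of class `sim_msa`: `msa` (named character vector of
#'   aligned rows) and `planted` (data.frame position, target_aa,
#'   consensus_aa, label).
#' @export
simulate_msa <- function(n_seqs, n_candidate_positions, conservation,
                         seed = 1L, length = 200L, target_id = "target") {
  if (n_seqs < 2) stop("'n_seqs' must be >= 2")
  assert_prob(conservation, "conservation")
  if (n_candidate_positions > length)
    stop("'n_candidate_positions' exceeds alignment length")
  with_seed(derive_seed(seed, "msa"), {
    cons <- sample(AA_STANDARD, length, replace = TRUE)
    n_other <- n_seqs - 1L
    rows <- matrix("", nrow = n_other, ncol = length)
    for (j in seq_len(length)) {
      agree <- runif(n_other) < conservation
      alt <- sample(setdiff(AA_STANDARD, cons[j]), n_other, replace = TRUE)
      rows[, j] <- ifelse(agree, cons[j], alt)
    }
    target <- cons
    planted_cols <- sort(sample(seq_len(length), n_candidate_positions))
    for (j in planted_cols) {
      target[j] <- sample(setdiff(AA_STANDARD, cons[j]), 1)
      n_agree <- max(1L, ceiling(conservation * n_other))
      who <- sample.int(n_other, n_agree)
      rows[who, j] <- cons[j]
      others <- setdiff(seq_len(n_other), who)
      if (length(others))
        rows[others, j] <- sample(setdiff(AA_STANDARD, cons[j]),
                                  length(others), replace = TRUE)
    }
  })
  msa <- c(setNames(paste(target, collapse = ""), target_id),
           setNames(apply(rows, 1, paste, collapse = ""),
                    sprintf("homolog%02d", seq_len(n_seqs - 1L))))
  planted <- data.frame(position = planted_cols,
                        target_aa = target[planted_cols],
                        consensus_aa = cons[planted_cols],
                        label = paste0(target[planted_cols], planted_cols,
                                       cons[planted_cols]),
                        stringsAsFactors = FALSE)
  structure(list(msa = msa, planted = planted), class = "sim_msa")
}
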