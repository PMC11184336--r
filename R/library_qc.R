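# Long-read genotyping of a shuffled mutant library against the
# designed-mutation catalogue, plus library-diversity statistics. Reads
# are filtered to full-length sequences matching the reference, then each
# designed codon position is scanned and classified WT / MUT / OTHER
# (codon-exact matching: a codon equal to neither the wild-type nor the
# designed mutant codon is OTHER and counts toward neither allele).

#' Write a designed-mutation table to TSV
#' @param design a `mutation_design` from [make_design()].
#' @param path output path.
#' @export
write_design_tsv <- function(design, path) {
  write_tsv(as.data.frame(design)[, c("mutation_id", "aa_pos_1based",
                                      "wt_aa", "mut_aa", "wt_codon",
                                      "mut_codon")], path)
}

#' Load and validate a designed-mutation table
#'
#' Cross-checks every row against the reference CDS: the stated wild-type
#' codon must match the reference at its position, mutation ids must be
#' unique, and each mutant codon must change the amino acid.
#'
#' @param path design TSV with columns `mutation_id`, `aa_pos_1based`,
#'   `wt_aa`, `mut_aa`, `wt_codon`, `mut_codon`.
#' @param reference reference CDS (character scalar or
#'   [make_reference()] output).
#' @return a validated `mutation_design`.
#' @export
load_design <- function(path, reference) {
  cds <- if (is.list(reference)) reference$cds else reference
  df <- read_tsv(path)
  need <- c("mutation_id", "aa_pos_1based", "wt_aa", "mut_aa",
            "wt_codon", "mut_codon")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("design table lacks columns: ", paste(missing, collapse = ", "))
  dup <- df$mutation_id[duplicated(df$mutation_id)]
  if (length(dup))
    stop("duplicate mutation_id in design: ", paste(unique(dup), collapse = ", "))
  cods <- codons_of(cds)
  for (i in seq_len(nrow(df))) {
    p <- df$aa_pos_1based[i]
    if (p < 1 || p > length(cods))
      stop("row ", df$mutation_id[i], ": position ", p, " outside reference")
    if (cods[p] != df$wt_codon[i])
      stop("row ", df$mutation_id[i], ": wt_codon ", df$wt_codon[i],
           " does not match reference codon ", cods[p], " at position ", p)
    if (df$wt_aa[i] == df$mut_aa[i])
      stop("row ", df$mutation_id[i], ": mut_aa equals wt_aa")
  }
  df$label <- paste0(df$wt_aa, df$aa_pos_1based, df$mut_aa)
  attr(df, "reference") <- cds
  class(df) <- c("mutation_design", "data.frame")
  df
}

# Project an alignment-filtered read onto reference coordinates: a string
# of reference length with read bases at aligned positions, '-' at
# deletions and uncovered flanks (insertions relative to the reference
# are dropped).
project_alignment <- function(aln, ref_len) {
  sr <- Biostrings::subject(aln)
  s <- Biostrings::start(sr); e <- Biostrings::end(sr)
  mid <- as.character(Biostrings::aligned(Biostrings::pattern(aln)))
  paste0(strrep("-", s - 1), mid, strrep("-", ref_len - e))
}

#' Filter one read for full-length agreement with the reference
#'
#' Auto-detects reverse-complement orientation. Same-length reads take a
#' Hamming fast path; length-discrepant reads are aligned semi-globally
#' (free end gaps, affine penalties) and projected onto reference
#' coordinates.
#'
#' @param read DNA string.
#' @param reference reference CDS (character or [make_reference()]
#'   output).
#' @param min_coverage minimum fraction of the reference covered by the
#'   alignment.
#' @param min_identity minimum identity over the aligned region.
#' @return list: `accepted`, `orientation` ("fwd"/"rc"), `identity`,
#'   `coverage`, `projected` (read in reference coordinates, NULL if
#'   rejected).
#' @export
filter_full_length <- function(read, reference, min_coverage = 0.95,
                               min_identity = 0.85) {
  res <- filter_reads(read, reference, min_coverage, min_identity)
  list(accepted = res$accepted[1], orientation = res$orientation[1],
       identity = res$identity[1], coverage = res$coverage[1],
       projected = if (res$accepted[1]) res$projected[1] else NULL)
}

#' Filter many reads for full-length agreement with the reference
#'
#' Vectorized [filter_full_length()]; the workhorse behind
#' [genotype_reads()].
#'
#' @inheritParams filter_full_length
#' @param reads character vector of DNA reads.
#' @return list with per-read vectors `accepted`, `orientation`,
#'   `identity`, `coverage`, and `projected` (reference-coordinate
#'   strings; `NA` where rejected).
#' @export
filter_reads <- function(reads, reference, min_coverage = 0.95,
                         min_identity = 0.85) {
  cds <- if (is.list(reference)) reference$cds else reference
  reads <- unname(unlist(reads))
  flags <- dna_flags_cpp(reads)
  if (any(flags == 2L))
    stop("reads contain non-DNA characters (first offender: ",
         which(flags == 2L)[1], ")")
  if (any(flags == 1L)) reads[flags == 1L] <- toupper(reads[flags == 1L])
  L <- nchar(cds)
  n <- length(reads)
  accepted <- logical(n); orientation <- rep("fwd", n)
  identity <- numeric(n); coverage <- numeric(n)
  projected <- rep(NA_character_, n)
  if (n == 0)
    return(list(accepted = accepted, orientation = orientation,
                identity = identity, coverage = coverage,
                projected = projected))
  same_len <- nchar(reads) == L
  # fast path: equal length, no indels possible -> Hamming identity
  if (any(same_len)) {
    idx <- which(same_len)
    mm_f <- mismatch_counts_cpp(reads[idx], cds)
    id_f <- 1 - mm_f / L
    need_rc <- id_f < min_identity
    id_r <- rep(-1, length(idx))
    if (any(need_rc)) {
      rc <- revcomp(reads[idx[need_rc]])
      id_r[need_rc] <- 1 - mismatch_counts_cpp(rc, cds) / L
    }
    use_rc <- id_r > id_f
    best <- pmax(id_f, id_r)
    accepted[idx] <- best >= min_identity
    identity[idx] <- best
    coverage[idx] <- 1
    orientation[idx] <- ifelse(use_rc, "rc", "fwd")
    ok <- idx[accepted[idx]]
    if (length(ok)) {
      fwd_ok <- ok[orientation[ok] == "fwd"]
      rc_ok <- ok[orientation[ok] == "rc"]
      projected[fwd_ok] <- reads[fwd_ok]
      if (length(rc_ok)) projected[rc_ok] <- revcomp(reads[rc_ok])
    }
  }
  # alignment path: length differs (indels, truncations)
  if (any(!same_len)) {
    refset <- Biostrings::DNAString(cds)
    for (i in which(!same_len)) {
      r <- Biostrings::DNAString(reads[i])
      a_f <- Biostrings::pairwiseAlignment(r, refset, type = "overlap")
      a_r <- Biostrings::pairwiseAlignment(Biostrings::reverseComplement(r),
                                           refset, type = "overlap")
      use_r <- Biostrings::score(a_r) > Biostrings::score(a_f)
      a <- if (use_r) a_r else a_f
      sr <- Biostrings::subject(a)
      cov <- (Biostrings::end(sr) - Biostrings::start(sr) + 1) / L
      idn <- Biostrings::nmatch(a) /
        max(1, Biostrings::end(sr) - Biostrings::start(sr) + 1)
      orientation[i] <- if (use_r) "rc" else "fwd"
      identity[i] <- idn; coverage[i] <- cov
      accepted[i] <- cov >= min_coverage && idn >= min_identity
      if (accepted[i]) projected[i] <- project_alignment(a, L)
    }
  }
  list(accepted = accepted, orientation = orientation, identity = identity,
       coverage = coverage, projected = projected)
}

states_matrix <- function(projected, design) {
  st <- codon_states_cpp(projected, 3L * design$aa_pos_1based - 2L,
                         design$wt_codon, design$mut_codon)
  colnames(st) <- design$mutation_id
  st  # 0 = WT, 1 = MUT, 2 = OTHER
}

#' Call the genotype of one filtered read
#'
#' Classifies every designed codon position of a reference-projected read
#' as WT (wild-type codon), MUT (designed mutant codon) or OTHER
#' (anything else, including deletion-disrupted codons), and returns the
#' set of MUT mutation ids.
#'
#' @param filtered a [filter_full_length()] result (or a
#'   reference-coordinate string).
#' @param design a `mutation_design`.
#' @return list: `genotype` (character vector of mutation ids), `states`
#'   (named "WT"/"MUT"/"OTHER" per designed position).
#' @export
call_genotype <- function(filtered, design) {
  proj <- if (is.list(filtered)) filtered$projected else filtered
  if (is.null(proj)) stop("read was rejected by the full-length filter")
  st <- states_matrix(proj, design)[1, ]
  states <- c("WT", "MUT", "OTHER")[st + 1L]
  names(states) <- design$mutation_id
  list(genotype = design$mutation_id[st == 1L], states = states)
}

#' Genotype a read set end to end
#'
#' Runs the full-length filter and codon scan over a read vector.
#'
#' @inheritParams filter_reads
#' @param design a `mutation_design` (carries the reference unless
#'   `reference` is given).
#' @param reference optional reference CDS override.
#' @return list of class `genotype_calls`: `per_read` (data.frame: read,
#'   accepted, orientation, identity, genotype key), `states` (integer
#'   matrix over passing reads, 0 WT / 1 MUT / 2 OTHER), `genotype_key`
#'   (comma-joined sorted mutation ids per passing read), `design`.
#' @export
genotype_reads <- function(reads, design, reference = attr(design, "reference"),
                           min_coverage = 0.95, min_identity = 0.85) {
  ids <- names(reads) %||% sprintf("read%06d", seq_along(reads))
  flt <- filter_reads(reads, reference, min_coverage, min_identity)
  pass <- which(flt$accepted)
  st <- if (length(pass)) states_matrix(flt$projected[pass], design)
        else matrix(integer(0), 0, nrow(design),
                    dimnames = list(NULL, design$mutation_id))
  key <- if (length(pass)) genotype_keys_cpp(st, design$mutation_id)
         else character(0)
  per_read <- data.frame(read = ids, accepted = flt$accepted,
                         orientation = flt$orientation,
                         identity = flt$identity, coverage = flt$coverage,
                         genotype = NA_character_, stringsAsFactors = FALSE)
  per_read$genotype[pass] <- key
  structure(list(per_read = per_read, states = st, genotype_key = key,
                 design = design,
                 n_total = length(reads), n_pass = length(pass)),
            class = "genotype_calls")
}

#' Per-mutation WT / MUT / OTHER read tallies
#'
#' @param calls a `genotype_calls` (or a 0/1/2 states matrix).
#' @return data.frame: `mutation_id`, `mut`, `wt`, `other` read counts.
#' @export
mutation_counts <- function(calls) {
  st <- if (inherits(calls, "genotype_calls")) calls$states else calls
  data.frame(mutation_id = colnames(st),
             mut = as.integer(colSums(st == 1L)),
             wt = as.integer(colSums(st == 0L)),
             other = as.integer(colSums(st == 2L)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Library-diversity statistics
#'
#' Unique variants are keyed by exact equality of their designed-mutation
#' sets; the mean mutation load is averaged over unique variants, not
#' over reads.
#'
#' @param calls a `genotype_calls` from [genotype_reads()] (or a
#'   character vector of genotype keys, one per passing read).
#' @return list of class `library_stats`: `total_reads`, `passing_reads`,
#'   `n_unique_variants`, `mean_mutation_load`, `variant_table`
#'   (genotype, load, support), `per_mutation` (from
#'   [mutation_counts()], when available).
#' @export
library_stats <- function(calls) {
  if (inherits(calls, "genotype_calls")) {
    keys <- calls$genotype_key
    total <- calls$n_total; passing <- calls$n_pass
    per_mut <- mutation_counts(calls)
  } else {
    keys <- as.character(calls)
    total <- passing <- length(keys)
    per_mut <- NULL
  }
  if (length(keys) == 0) {
    vt <- data.frame(genotype = character(0), load = integer(0),
                     support = integer(0), stringsAsFactors = FALSE)
    return(structure(list(total_reads = total, passing_reads = passing,
                          n_unique_variants = 0L, mean_mutation_load = 0,
                          variant_table = vt, per_mutation = per_mut),
                     class = "library_stats"))
  }
  tab <- table(keys)
  geno <- names(tab)
  load <- ifelse(geno == "", 0L, lengths(strsplit(geno, ",")))
  vt <- data.frame(genotype = geno, load = as.integer(load),
                   support = as.integer(tab), stringsAsFactors = FALSE,
                   row.names = NULL)
  vt <- vt[order(-vt$support, vt$genotype), , drop = FALSE]
  rownames(vt) <- NULL
  structure(list(total_reads = total, passing_reads = passing,
                 n_unique_variants = nrow(vt),
                 mean_mutation_load = mean(vt$load),
                 variant_table = vt, per_mutation = per_mut),
            class = "library_stats")
}

#' @export
print.library_stats <- function(x, ...) {
  cat("Library statistics\n")
  cat("  reads:          ", x$passing_reads, "passing /", x$total_reads,
      "total\n")
  cat("  unique variants:", x$n_unique_variants, "\n")
  cat("  mean load:      ", signif(x$mean_mutation_load, 4),
      "designed mutations per unique variant\n")
  invisible(x)
}

#' Size of the combinatorial variant space
#'
#' Number of distinct variants carrying between 1 and `max_load` of
#' `n_mutations` designed substitutions, in exact integer arithmetic:
#' the sum of binomial coefficients C(n, k) for k = 1..max_load, or
#' 2^n - 1 when `max_load = "all"`.
#'
#' @param n_mutations catalogue size (e.g. 108).
#' @param max_load maximum mutations per variant, or `"all"`.
#' @return list of class `combinatorial_space`: `count` (exact decimal
#'   string), `approx` (numeric), `n_mutations`, `max_load`.
#' @export
combinatorial_space <- function(n_mutations, max_load) {
  n <- assert_count(n_mutations, "n_mutations")
  if (identical(max_load, "all")) {
    total <- big_from_int(1)
    for (i in seq_len(n)) total <- big_mul_small(total, 2)
    total <- big_sub_small(total, 1)
    k <- "all"
  } else {
    k <- assert_count(max_load, "max_load")
    if (k > n) stop("'max_load' cannot exceed 'n_mutations'")
    total <- big_from_int(0)
    term <- big_from_int(1)  # C(n, 0)
    for (i in seq_len(k)) {
      term <- big_div_small(big_mul_small(term, n - i + 1), i)
      total <- big_add(total, term)
    }
  }
  structure(list(count = big_to_string(total), approx = big_to_num(total),
                 n_mutations = n, max_load = k),
            class = "combinatorial_space")
}

#' @export
print.combinatorial_space <- function(x, ...) {
  cat("Variants with 1..", ifelse(identical(x$max_load, "all"),
                                  x$n_mutations, x$max_load),
      " of ", x$n_mutations, " designed mutations: ", x$count,
      " (~", format(x$approx, digits = 4), ")\n", sep = "")
  invisible(x)
}
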