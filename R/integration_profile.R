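# Transposon integration-site recovery from ITR-genome junction reads
# and the downstream safety profile: unsigned distance to the nearest
# transcription start site and genomic-context classification
# (coding_exon > transcript_noncoding > outside_transcript), each
# compared with a matched uniform-random baseline.
#
# Coordinates: insertion points and junction boundaries are 0-based
# between-base coordinates internally; GFF3 input and BED output follow
# their respective standards.

#' Extract genomic fragments from ITR-genome junction reads
#'
#' A junction read starts with a (possibly far-end truncated) suffix of
#' the transposon-terminal probe followed by genomic sequence. The
#' longest probe-suffix prefix of at least `min_itr_match` bases is
#' trimmed; reverse-complement reads are detected and returned in probe
#' orientation. Reads that are transposon over their whole length, reads
#' with no probe match, and fragments shorter than `min_genomic_len` are
#' discarded.
#'
#' @param reads named character vector of junction reads.
#' @param itr_probe transposon-terminal sequence expected at the
#'   junction (junction-proximal end = last base).
#' @param min_itr_match minimum probe bases required at the read start.
#' @param min_genomic_len minimum retained genomic fragment length.
#' @return data.frame: `read`, `fragment`, `orientation`
#'   ("fwd"/"rc"), `probe_bases`.
#' @export
extract_junctions <- function(reads, itr_probe, min_itr_match = 12,
                              min_genomic_len = 20) {
  if (is.null(itr_probe) || !nzchar(itr_probe)) stop("empty ITR probe")
  probe <- toupper(itr_probe)
  plen <- nchar(probe)
  ids <- names(reads) %||% sprintf("jread%05d", seq_along(reads))
  match_len <- function(r) {
    # longest k with prefix(read, k) == suffix(probe, k)
    top <- min(plen, nchar(r))
    for (k in top:min_itr_match) {
      if (substr(r, 1, k) == substr(probe, plen - k + 1, plen)) return(k)
    }
    0L
  }
  out <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    r <- toupper(reads[[i]])
    ori <- "fwd"; k <- match_len(r)
    if (k == 0) {
      rrc <- revcomp(r)
      k <- match_len(rrc)
      if (k > 0) { r <- rrc; ori <- "rc" }
    }
    if (k == 0) next                       # no junction anchor
    frag <- substr(r, k + 1, nchar(r))
    if (nchar(frag) < min_genomic_len) next  # vector-only or too short
    out[[i]] <- data.frame(read = ids[i], fragment = frag,
                           orientation = ori, probe_bases = k,
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(read = character(0), fragment = character(0),
                      orientation = character(0), probe_bases = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Map genomic fragments by exact search
#'
#' Desk-scale mapper for toy genomes: each fragment is searched exactly
#' against both strands of every contig. Fragments with more than one
#' total hit are flagged `multimap`, fragments with none `unmapped`;
#' both are excluded from site calling. The junction boundary is the
#' between-base coordinate at which the transposon abuts the genome: for
#' a forward hit the fragment runs rightward from the junction
#' (`side = "right"`), for a reverse-complement hit leftward
#' (`side = "left"`).
#'
#' @param fragments [extract_junctions()] output (or a character vector).
#' @param genome named character vector of contig sequences.
#' @return data.frame: `fragment_id`, `contig`, `boundary` (0-based
#'   between-base), `side`, `status` ("mapped"/"multimap"/"unmapped").
#' @export
map_fragments <- function(fragments, genome) {
  frags <- if (is.data.frame(fragments)) fragments$fragment else unname(fragments)
  ids <- if (is.data.frame(fragments)) fragments$read
         else names(fragments) %||% sprintf("frag%05d", seq_along(fragments))
  empty <- data.frame(fragment_id = character(0), contig = character(0),
                      boundary = integer(0), side = character(0),
                      status = character(0), stringsAsFactors = FALSE)
  n <- length(frags)
  if (n == 0) return(empty)
  genome <- vapply(genome, toupper, character(1))
  # seed index: the first W bases of every fragment at a common width,
  # searched on both strands in one pass, then verified full length
  W <- min(nchar(frags))
  lens <- nchar(frags)
  seeds <- Biostrings::DNAStringSet(substr(frags, 1, W))
  pd_f <- Biostrings::PDict(seeds)
  pd_r <- Biostrings::PDict(Biostrings::reverseComplement(seeds))
  hit_ct <- integer(n)
  hit <- data.frame(contig = rep(NA_character_, n), boundary = NA_integer_,
                    side = NA_character_, stringsAsFactors = FALSE)
  for (ctg in names(genome)) {
    subj <- Biostrings::DNAString(genome[[ctg]])
    sf <- Biostrings::startIndex(Biostrings::matchPDict(pd_f, subj))
    sr <- Biostrings::endIndex(Biostrings::matchPDict(pd_r, subj))
    for (i in seq_len(n)) {
      for (s in sf[[i]]) {  # forward: fragment runs rightward from junction
        if (substring(genome[[ctg]], s, s + lens[i] - 1) == frags[i]) {
          hit_ct[i] <- hit_ct[i] + 1L
          hit$contig[i] <- ctg; hit$boundary[i] <- s - 1L
          hit$side[i] <- "right"
        }
      }
      for (e in sr[[i]]) {  # seed is the junction-proximal end of the rc hit
        if (e >= lens[i] &&
            substring(genome[[ctg]], e - lens[i] + 1, e) == revcomp(frags[i])) {
          hit_ct[i] <- hit_ct[i] + 1L
          hit$contig[i] <- ctg; hit$boundary[i] <- e
          hit$side[i] <- "left"
        }
      }
    }
  }
  status <- ifelse(hit_ct == 0, "unmapped",
                   ifelse(hit_ct > 1, "multimap", "mapped"))
  bad <- status != "mapped"
  hit$contig[bad] <- NA_character_
  hit$boundary[bad] <- NA_integer_
  hit$side[bad] <- NA_character_
  data.frame(fragment_id = ids, contig = hit$contig, boundary = hit$boundary,
             side = hit$side, status = status, stringsAsFactors = FALSE)
}

#' Import pre-mapped junction loci
#'
#' Accepts a tabular alignment export with columns `contig`,
#' `pos_1based` (leftmost aligned base), `strand` (+/-) and
#' `fragment_id`, plus the fragment length column `width` (or per-row
#' end). Converts to the junction-boundary convention used by
#' [map_fragments()].
#'
#' @param path TSV path.
#' @return data.frame compatible with [cluster_sites()].
#' @export
read_mapped_loci <- function(path) {
  df <- read_tsv(path)
  need <- c("contig", "pos_1based", "strand", "fragment_id", "width")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("mapped-loci table lacks columns: ", paste(missing, collapse = ", "))
  side <- ifelse(df$strand == "+", "right", "left")
  boundary <- ifelse(df$strand == "+", df$pos_1based - 1L,
                     df$pos_1based - 1L + df$width)
  data.frame(fragment_id = df$fragment_id, contig = df$contig,
             boundary = as.integer(boundary), side = side,
             status = "mapped", stringsAsFactors = FALSE)
}

# greedy single-linkage chain within merge_window; representative = the
# boundary with the largest summed support (ties: leftmost)
collapse_boundaries <- function(boundary, window) {
  o <- order(boundary)
  b <- boundary[o]
  grp <- cumsum(c(1L, diff(b) > window))
  reps <- tapply(b, grp, function(v) {
    tb <- table(v)
    as.integer(names(tb)[which.max(tb)])
  })
  support <- as.integer(table(grp))
  data.frame(boundary = as.integer(reps), support = support,
             row.names = NULL)
}

#' Cluster junction loci into deduplicated insertion sites
#'
#' Loci on the same junction side within `merge_window` bases merge
#' (support summed, representative = modal boundary). A right-side
#' cluster at boundary `p` and a left-side cluster at exactly
#' `p + tsd_length` are two readouts of one insertion and collapse into
#' a single site at point `p` with its target-site duplication extracted
#' from the genome. Unpaired clusters become single-sided sites.
#'
#' @param loci mapped loci from [map_fragments()] (rows with
#'   `status == "mapped"` are used).
#' @param genome named character vector of contigs (TSD extraction).
#' @param merge_window same-side merge distance in bases.
#' @param tsd_length expected target-site duplication length.
#' @return data.frame of class `insertion_sites`: `contig`, `point`
#'   (0-based between-base insertion coordinate), `strand`, `tsd`,
#'   `support`, `n_sides`.
#' @export
cluster_sites <- function(loci, genome, merge_window = 5, tsd_length = 8) {
  loci <- loci[loci$status == "mapped", , drop = FALSE]
  empty <- data.frame(contig = character(0), point = integer(0),
                      strand = character(0), tsd = character(0),
                      support = integer(0), n_sides = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(loci) == 0) { class(empty) <- c("insertion_sites", "data.frame"); return(empty) }
  res <- list()
  for (ctg in unique(loci$contig)) {
    sub <- loci[loci$contig == ctg, ]
    right <- if (any(sub$side == "right"))
      collapse_boundaries(sub$boundary[sub$side == "right"], merge_window)
      else data.frame(boundary = integer(0), support = integer(0))
    left <- if (any(sub$side == "left"))
      collapse_boundaries(sub$boundary[sub$side == "left"], merge_window)
      else data.frame(boundary = integer(0), support = integer(0))
    used_left <- logical(nrow(left))
    gseq <- genome[[ctg]]
    for (i in seq_len(nrow(right))) {
      p <- right$boundary[i]
      j <- which(!used_left & left$boundary == p + tsd_length)
      if (length(j)) {
        j <- j[1]; used_left[j] <- TRUE
        res[[length(res) + 1L]] <- data.frame(
          contig = ctg, point = p, strand = "+",
          tsd = substr(gseq, p + 1, p + tsd_length),
          support = right$support[i] + left$support[j], n_sides = 2L,
          stringsAsFactors = FALSE)
      } else {
        res[[length(res) + 1L]] <- data.frame(
          contig = ctg, point = p, strand = "+",
          tsd = substr(gseq, p + 1, p + tsd_length),
          support = right$support[i], n_sides = 1L,
          stringsAsFactors = FALSE)
      }
    }
    for (j in which(!used_left)) {
      p <- left$boundary[j] - tsd_length
      res[[length(res) + 1L]] <- data.frame(
        contig = ctg, point = p, strand = "-",
        tsd = substr(gseq, p + 1, p + tsd_length),
        support = left$support[j], n_sides = 1L, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  out <- out[order(out$contig, out$point), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("insertion_sites", "data.frame")
  out
}

# ---- annotation handling -------------------------------------------------

#' Read transcript annotation from GFF3
#'
#' @param path GFF3 path with `mRNA`/`transcript` and `CDS` records.
#' @return list: `transcripts` (GRanges), `cds` (GRanges) — the
#'   structure produced by [simulate_genome_and_insertions()].
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  tx <- gr[gr$type %in% c("mRNA", "transcript")]
  cds <- gr[gr$type == "CDS"]
  list(transcripts = tx, cds = cds)
}

#' Strand-aware TSS coordinates of an annotation
#'
#' The transcription start of a plus-strand transcript is the between-base
#' coordinate just 5' of its first base; for a minus-strand transcript,
#' just 3' of its last base.
#'
#' @param annotation list with a `transcripts` GRanges.
#' @return data.frame: `contig`, `point` (0-based between-base TSS).
#' @export
annotation_tss <- function(annotation) {
  tx <- annotation$transcripts
  pos <- ifelse(as.character(BiocGenerics::strand(tx)) == "-",
                BiocGenerics::end(tx), BiocGenerics::start(tx) - 1L)
  data.frame(contig = as.character(GenomeInfoDb::seqnames(tx)),
             point = as.integer(pos), stringsAsFactors = FALSE)
}

#' Unsigned distance to the nearest transcription start site
#'
#' TSSs are strand-aware (transcript 5' ends). A site exactly at a TSS
#' has distance 0. Sites on contigs absent from the annotation get `NA`
#' with a warning and are excluded from summaries.
#'
#' @param sites an `insertion_sites` data frame (or any data frame with
#'   `contig` and `point`).
#' @param annotation list with a `transcripts` GRanges (see
#'   [read_annotation()]).
#' @return numeric vector of distances in bases, parallel to `sites`.
#' @export
distance_to_tss <- function(sites, annotation) {
  tss <- annotation_tss(annotation)
  out <- rep(NA_real_, nrow(sites))
  for (ctg in unique(sites$contig)) {
    idx <- which(sites$contig == ctg)
    tp <- sort(tss$point[tss$contig == ctg])
    if (!length(tp)) next
    pts <- sites$point[idx]
    k <- findInterval(pts, tp)
    d_lo <- ifelse(k >= 1, pts - tp[pmax(k, 1)], Inf)
    d_hi <- ifelse(k < length(tp), tp[pmin(k + 1, length(tp))] - pts, Inf)
    out[idx] <- pmin(d_lo, d_hi)
  }
  if (anyNA(out))
    warning(sum(is.na(out)), " site(s) on contigs absent from the ",
            "annotation; excluded from summaries")
  out
}

#' Genomic-context class of insertion sites
#'
#' The base immediately 3' of the insertion point is classified with
#' precedence `coding_exon` > `transcript_noncoding` >
#' `outside_transcript`.
#'
#' @inheritParams distance_to_tss
#' @param annotation list with `transcripts` and `cds` GRanges.
#' @return character vector of context classes, parallel to `sites`.
#' @export
classify_context <- function(sites, annotation) {
  if (nrow(sites) == 0) return(character(0))
  gr <- GenomicRanges::GRanges(sites$contig,
                               IRanges::IRanges(sites$point + 1L,
                                                sites$point + 1L))
  in_cds <- GenomicRanges::countOverlaps(gr, annotation$cds,
                                         ignore.strand = TRUE) > 0
  in_tx <- GenomicRanges::countOverlaps(gr, annotation$transcripts,
                                        ignore.strand = TRUE) > 0
  ifelse(in_cds, "coding_exon",
         ifelse(in_tx, "transcript_noncoding", "outside_transcript"))
}

CONTEXT_CLASSES <- c("coding_exon", "transcript_noncoding",
                     "outside_transcript")

context_fractions <- function(classes) {
  tab <- table(factor(classes, levels = CONTEXT_CLASSES))
  as.numeric(tab) / max(1, length(classes)) -> fr
  setNames(fr, CONTEXT_CLASSES)
}

#' Integration safety profile vs a uniform-random baseline
#'
#' Computes per-site TSS distances and context classes, summarises them
#' (median distance with bootstrap SE over sites; class fractions), and
#' compares against `n_random` uniform positions drawn over the same
#' contigs (the matched random baseline), reporting observed/baseline
#' fraction ratios.
#'
#' @param sites an `insertion_sites` data frame (>= 1 site).
#' @param annotation list with `transcripts` and `cds` GRanges.
#' @param genome named character vector of contig sequences (supplies
#'   contig lengths for the baseline).
#' @param n_random baseline positions.
#' @param n_bootstrap bootstrap resamples for the median's SE (0 = no
#'   SE, reported as `NA`).
#' @param seed seed for baseline and bootstrap.
#' @return list of class `integration_profile`: `distances`, `classes`,
#'   `median_tss_distance`, `median_tss_se`, `fractions`, `baseline`
#'   (same summaries for the random sites), `fraction_ratio`, `n_sites`.
#' @export
profile_summary <- function(sites, annotation, genome, n_random = 10000,
                            n_bootstrap = 200, seed = 1L) {
  if (nrow(sites) == 0) stop("empty site list")
  d <- distance_to_tss(sites, annotation)
  cls <- classify_context(sites, annotation)
  keep <- !is.na(d)
  med <- median(d[keep])
  se <- NA_real_
  contig_len <- nchar(genome)
  with_seed(derive_seed(seed, "bootstrap"), {
    if (n_bootstrap > 0) {
      meds <- vapply(seq_len(n_bootstrap), function(b)
        median(sample(d[keep], sum(keep), replace = TRUE)), numeric(1))
      se <- sd(meds)
    }
  })
  with_seed(derive_seed(seed, "baseline"), {
    ctg <- sample(names(genome), n_random, replace = TRUE,
                  prob = contig_len / sum(contig_len))
    pt <- floor(runif(n_random) * contig_len[ctg])
    rnd <- data.frame(contig = ctg, point = as.integer(pt),
                      stringsAsFactors = FALSE)
  })
  rd <- suppressWarnings(distance_to_tss(rnd, annotation))
  rcls <- classify_context(rnd, annotation)
  fr <- context_fractions(cls)
  rfr <- context_fractions(rcls)
  structure(list(distances = d, classes = cls,
                 median_tss_distance = med, median_tss_se = se,
                 fractions = fr,
                 baseline = list(median_tss_distance = median(rd, na.rm = TRUE),
                                 fractions = rfr, n_random = n_random),
                 fraction_ratio = fr / rfr,
                 n_sites = nrow(sites)),
            class = "integration_profile")
}

#' @export
print.integration_profile <- function(x, ...) {
  cat("Integration profile over", x$n_sites, "sites\n")
  cat(sprintf("  median TSS distance: %.0f b (bootstrap SE %.0f)\n",
              x$median_tss_distance, x$median_tss_se))
  for (k in names(x$fractions))
    cat(sprintf("  %-21s %.3f (baseline %.3f, ratio %.2f)\n", k,
                x$fractions[k], x$baseline$fractions[k], x$fraction_ratio[k]))
  invisible(x)
}

#' Write insertion sites to BED
#'
#' BED6 with 0-based half-open intervals spanning the TSD, the TSD
#' sequence as name and read support as score.
#'
#' @param sites an `insertion_sites` data frame.
#' @param path output path.
#' @export
write_sites_bed <- function(sites, path) {
  tsd_w <- nchar(sites$tsd)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s", sites$contig, sites$point,
                   sites$point + tsd_w, sites$tsd, sites$support,
                   sites$strand)
  writeLines(lines, path)
  invisible(path)
}
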