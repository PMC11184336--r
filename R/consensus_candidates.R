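# Candidate hyperactive substitutions from a protein multiple alignment:
# conserved column residues that the target sequence lacks. Frequencies
# are computed over informative residues only (gaps and ambiguity codes
# X/B/Z are dropped from denominators), and the consensus is taken over
# the NON-target rows, since the question is what the homolog family
# agrees on that the target does not carry.

MSA_IGNORE <- c("-", ".", "X", "B", "Z", "*")

msa_matrix <- function(msa) {
  if (is(msa, "AAStringSet") || is(msa, "XStringSet")) {
    seqs <- as.character(msa)
    names(seqs) <- names(msa)
  } else seqs <- msa
  w <- unique(nchar(seqs))
  if (length(w) != 1)
    stop("ragged alignment: rows have differing widths (",
         paste(w, collapse = ", "), ")")
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(m) <- names(seqs)
  m
}

#' Per-column residue frequencies of a protein alignment
#'
#' @param msa aligned sequences: a named character vector of equal-width
#'   rows or an `AAStringSet`.
#' @return list of class `alignment_profile`: `freq` (20 x n_col matrix
#'   of residue frequencies over informative characters), `coverage`
#'   (fraction of informative rows per column), `all_gap` (logical per
#'   column), `n_seq`, `n_col`.
#' @export
column_frequencies <- function(msa) {
  m <- msa_matrix(msa)
  n_col <- ncol(m); n_seq <- nrow(m)
  freq <- matrix(0, nrow = length(AA_STANDARD), ncol = n_col,
                 dimnames = list(AA_STANDARD, NULL))
  coverage <- numeric(n_col)
  for (j in seq_len(n_col)) {
    col <- m[, j]
    inf <- col[!col %in% MSA_IGNORE]
    coverage[j] <- length(inf) / n_seq
    if (length(inf)) {
      tab <- table(factor(inf, levels = AA_STANDARD))
      freq[, j] <- as.numeric(tab) / length(inf)
    }
  }
  structure(list(freq = freq, coverage = coverage,
                 all_gap = coverage == 0, n_seq = n_seq, n_col = n_col),
            class = "alignment_profile")
}

#' Candidate substitutions: conserved residues the target lacks
#'
#' Scans each alignment column for a consensus residue (computed over all
#' rows except the target) reaching `min_conservation` among informative
#' characters with at least `min_coverage` informative rows, and reports
#' columns where the target carries a different standard residue.
#' Positions are reported in target-sequence numbering (target gap
#' columns are skipped). Consensus ties resolve to the alphabetically
#' first residue.
#'
#' @param msa aligned sequences (named character vector or AAStringSet).
#' @param target_id name of the target row.
#' @param min_conservation consensus frequency threshold, in (0.5, 1].
#' @param min_coverage minimum informative-row fraction per column.
#' @return data frame of class `candidate_substitutions`: `position`
#'   (target numbering, 1-based), `wt` (target residue), `consensus`,
#'   `frequency`, `coverage`, `label` (e.g. `"V356L"`), sorted by
#'   position.
#' @export
candidate_substitutions <- function(msa, target_id,
                                    min_conservation = 0.6,
                                    min_coverage = 0.5) {
  m <- msa_matrix(msa)
  if (!target_id %in% rownames(m))
    stop("target_id '", target_id, "' not found in alignment")
  if (min_conservation <= 0.5 || min_conservation > 1)
    stop("'min_conservation' must lie in (0.5, 1]")
  target <- m[target_id, ]
  others <- m[setdiff(rownames(m), target_id), , drop = FALSE]
  prof <- column_frequencies(apply(others, 1, paste, collapse = ""))
  tpos <- cumsum(!target %in% c("-", "."))
  keep <- integer(0); wt <- character(0); cons <- character(0)
  fr <- numeric(0); cov <- numeric(0)
  for (j in seq_len(ncol(m))) {
    if (target[j] %in% MSA_IGNORE) next
    if (prof$all_gap[j] || prof$coverage[j] < min_coverage) next
    f <- prof$freq[, j]
    best <- which.max(f)  # ties: alphabetical (matrix row order)
    if (f[best] < min_conservation) next
    cres <- AA_STANDARD[best]
    if (cres == target[j]) next
    keep <- c(keep, tpos[j]); wt <- c(wt, target[j]); cons <- c(cons, cres)
    fr <- c(fr, unname(f[best])); cov <- c(cov, prof$coverage[j])
  }
  out <- data.frame(position = keep, wt = wt, consensus = cons,
                    frequency = fr, coverage = cov,
                    label = if (length(keep)) paste0(wt, keep, cons)
                            else character(0),
                    stringsAsFactors = FALSE)
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_substitutions", "data.frame")
  out
}

#' Read an aligned protein FASTA
#' @param path aligned FASTA path.
#' @return named character vector of aligned rows.
#' @export
read_msa_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}
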