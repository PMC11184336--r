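# Per-mutation enrichment between the naive (preselection) and sorted
# populations. For each designed mutation:
#
#   F   = Reads_mut / (Reads_mut + Reads_wt)        (per population)
#   E   = F_sort / F_naive
#   WES = ln(E) * sqrt(Reads_mut,sort + Reads_mut,naive)
#
# Reads whose codon at a position is OTHER are excluded from that
# position's denominator. With the default pseudocount 0.5 the additive
# correction enters F only; the sqrt weight always uses raw mutant read
# counts, so WES keeps the literal formula's scale. pseudocount = 0
# reproduces the literal formulas and errors on zero denominators.

#' Per-mutation frequency F
#'
#' `F = (reads_mut + a) / (reads_mut + reads_wt + 2a)` with pseudocount
#' `a`.
#'
#' @param reads_mut,reads_wt non-negative read counts (vectorized).
#' @param pseudocount additive count `a` (default 0).
#' @return frequency in `[0, 1]`.
#' @export
mutation_frequency <- function(reads_mut, reads_wt, pseudocount = 0) {
  if (any(reads_mut < 0) || any(reads_wt < 0))
    stop("read counts must be non-negative")
  if (pseudocount < 0) stop("'pseudocount' must be >= 0")
  if (pseudocount == 0 && any(reads_mut + reads_wt == 0))
    stop("undefined frequency: reads_mut + reads_wt == 0 with pseudocount 0; ",
         "supply a positive pseudocount")
  (reads_mut + pseudocount) / (reads_mut + reads_wt + 2 * pseudocount)
}

#' Crude enrichment E
#'
#' `E = F_sort / F_naive`.
#'
#' @param F_sort,F_naive mutation frequencies (vectorized).
#' @return enrichment ratio.
#' @export
crude_enrichment <- function(F_sort, F_naive) {
  if (any(F_naive == 0))
    stop("F_naive == 0: crude enrichment undefined; recompute frequencies ",
         "with a positive pseudocount")
  F_sort / F_naive
}

#' Weighted enrichment score WES
#'
#' `WES = ln(E) * sqrt(reads_mut_sort + reads_mut_naive)`. The square
#' root of the summed mutant read counts weights well-sampled mutations
#' more heavily than rarely observed ones.
#'
#' @param E crude enrichment (> 0).
#' @param reads_mut_sort,reads_mut_naive raw mutant read counts.
#' @return the weighted enrichment score (vectorized).
#' @export
weighted_enrichment <- function(E, reads_mut_sort, reads_mut_naive) {
  if (any(E <= 0))
    stop("E must be > 0 (apply a pseudocount upstream for zero counts)")
  log(E) * sqrt(reads_mut_sort + reads_mut_naive)
}

#' Full per-mutation enrichment table
#'
#' Joins naive and sorted per-mutation counts over the design, computes
#' F, E and WES per designed amino-acid substitution (designed codons
#' encoding the same substitution are merged), and ranks by WES
#' descending with ties broken by mutation id. Records whose WES is
#' undefined under `pseudocount = 0` are flagged, not dropped.
#'
#' @param naive_counts,sorted_counts data frames with columns
#'   `mutation_id`, `mut`, `wt` (from [mutation_counts()]).
#' @param design a `mutation_design`.
#' @param pseudocount additive count applied inside F (default 0.5); the
#'   WES weight always uses raw counts.
#' @return data.frame of class `enrichment_table`: count columns,
#'   `F_naive`, `F_sort`, `E`, `WES`, `rank`, `undefined`.
#' @export
enrichment_table <- function(naive_counts, sorted_counts, design,
                             pseudocount = 0.5) {
  stopifnot(inherits(design, "mutation_design"))
  for (nm in c("naive", "sorted")) {
    cc <- if (nm == "naive") naive_counts else sorted_counts
    bad <- setdiff(cc$mutation_id, design$mutation_id)
    if (length(bad))
      stop(nm, " counts carry ids absent from the design: ",
           paste(bad, collapse = ", "))
  }
  idx_n <- match(design$mutation_id, naive_counts$mutation_id)
  idx_s <- match(design$mutation_id, sorted_counts$mutation_id)
  df <- data.frame(
    mutation_id = design$mutation_id, label = design$label,
    reads_mut_naive = ifelse(is.na(idx_n), 0L, naive_counts$mut[idx_n]),
    reads_wt_naive = ifelse(is.na(idx_n), 0L, naive_counts$wt[idx_n]),
    reads_mut_sort = ifelse(is.na(idx_s), 0L, sorted_counts$mut[idx_s]),
    reads_wt_sort = ifelse(is.na(idx_s), 0L, sorted_counts$wt[idx_s]),
    stringsAsFactors = FALSE)
  # merge designed codons that encode the same amino-acid substitution
  if (anyDuplicated(df$label)) {
    agg <- aggregate(df[, 3:6], by = list(label = df$label), FUN = sum)
    first <- !duplicated(df$label)
    agg$mutation_id <- df$mutation_id[first][match(agg$label, df$label[first])]
    df <- agg[, c("mutation_id", "label", "reads_mut_naive",
                  "reads_wt_naive", "reads_mut_sort", "reads_wt_sort")]
  }
  a <- pseudocount
  den_n <- df$reads_mut_naive + df$reads_wt_naive
  den_s <- df$reads_mut_sort + df$reads_wt_sort
  undefined <- logical(nrow(df))
  if (a == 0) {
    undefined <- den_n == 0 | den_s == 0 | df$reads_mut_naive == 0 |
      df$reads_mut_sort == 0
    Fn <- Fs <- rep(NA_real_, nrow(df))
    ok <- !undefined
    Fn[ok] <- df$reads_mut_naive[ok] / den_n[ok]
    Fs[ok] <- df$reads_mut_sort[ok] / den_s[ok]
  } else {
    Fn <- (df$reads_mut_naive + a) / (den_n + 2 * a)
    Fs <- (df$reads_mut_sort + a) / (den_s + 2 * a)
  }
  E <- Fs / Fn
  WES <- log(E) * sqrt(df$reads_mut_sort + df$reads_mut_naive)
  undefined <- undefined | !is.finite(WES)
  df$F_naive <- Fn; df$F_sort <- Fs; df$E <- E; df$WES <- WES
  df$undefined <- undefined
  ord <- order(undefined, -ifelse(is.finite(WES), WES, -Inf), df$mutation_id)
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  class(df) <- c("enrichment_table", "data.frame")
  df
}

#' @importFrom stats aggregate
NULL
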