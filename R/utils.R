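# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-stage random stream from one master seed
#'
#' Each generator draws from its own stream so that adding reads to one
#' stage never perturbs another. The derivation is a fixed affine map of
#' the master seed per named stage, folded into the 31-bit signed range R
#' accepts.
#'
#' @param seed master seed (integer).
#' @param stage stage name, one of the names in the internal offset table.
#' @return an integer seed, deterministic in `(seed, stage)`.
#' @export
derive_seed <- function(seed, stage) {
  offsets <- c(reference = 101L, design = 211L, library = 307L,
               sort = 401L, genome = 503L, msa = 601L,
               baseline = 701L, bootstrap = 809L, effects = 907L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) * 7919 + offsets[[stage]]) %% 2147483647)
}

with_seed <- function(seed, code) withr::with_seed(as.integer(seed), code)

DNA_BASES <- c("A", "C", "G", "T")
AA_STANDARD <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")

# all 64 codons and their amino acids ('*' = stop), from the standard code
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  data.frame(codon = names(gc), aa = unname(gc), stringsAsFactors = FALSE)
}

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

translate_cds <- function(cds) {
  as.character(Biostrings::translate(Biostrings::DNAStringSet(cds),
                                     if.fuzzy.codon = "X"))
}

codons_of <- function(cds) {
  n <- nchar(cds) %/% 3L
  substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTNacgtn]", x)
  if (any(bad)) stop(what, " contains non-DNA characters (first offender: ",
                     which(bad)[1], ")")
  invisible(toupper(x))
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop("'", name, "' must be a single probability in [0, 1]")
  invisible(x)
}

assert_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x))
    stop("'", name, "' must be a single integer >= ", min)
  invisible(as.integer(x))
}

# signif() that leaves integers and NAs alone; used for stable serialization
signif6 <- function(x) {
  if (!is.numeric(x) || is.integer(x)) return(x)
  signif(x, 6)
}
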