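# Readers/writers for the standard formats the pipeline exchanges.
# FASTA/FASTQ go through Biostrings; GFF3 through rtracklayer; tables are
# plain TSV with numerics serialized at 6 significant digits so repeated
# runs under one seed diff cleanly.

#' Write sequences to FASTA
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

write_fasta_aa <- function(seqs, path) {
  x <- Biostrings::AAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write reads to FASTQ (constant Q40 qualities)
#'
#' Circular-consensus style reads carry no per-base quality model here;
#' a flat high quality is written. A zero-read input yields a valid empty
#' file.
#'
#' @param reads character vector of read sequences (names become ids).
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  if (length(reads) == 0) {
    file.create(path)
    return(invisible(path))
  }
  ids <- names(reads) %||% paste0("read", seq_along(reads))
  x <- Biostrings::DNAStringSet(unname(unlist(reads)))
  names(x) <- ids
  qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(x)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read sequences from FASTA or FASTQ
#'
#' Format is sniffed from the first non-empty line. Returns a named
#' character vector; an empty file returns `character(0)`.
#'
#' @param path input path.
#' @export
read_reads <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) return(character(0))
  first <- readLines(path, n = 1)
  fmt <- if (startsWith(first, "@")) "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a data frame to TSV (numerics at 6 significant digits)
#' @param df data frame.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  df[] <- lapply(df, signif6)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path input path.
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a list to pretty JSON with unboxed scalars
#' @param x list to serialize.
#' @param path output path.
#' @export
write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
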