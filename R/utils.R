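#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a nucleotide string
#'
#' Plain-character convenience wrapper around [Biostrings::reverseComplement()].
#' `N` is preserved.
#'
#' @param x character vector of sequences over A/C/G/T/N.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Fractional GC content of a sequence
#'
#' @param x character vector of sequences.
#' @return numeric vector in \[0, 1\]; G and C counted over all bases.
#' @export
gc_content <- function(x) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)
  vapply(chars, function(ch) {
    if (length(ch) == 0L) return(NA_real_)
    sum(ch %in% c("G", "C")) / length(ch)
  }, numeric(1))
}

random_dna <- function(n_bases) {
  paste(sample(DNA_BASES, n_bases, replace = TRUE), collapse = "")
}

#' Construct a read set
#'
#' A lightweight container for sequencing reads: parallel vectors of
#' identifiers and sequences plus a list of integer phred quality vectors.
#'
#' @param id character vector of read identifiers (unique).
#' @param seq character vector of nucleotide sequences (A/C/G/T/N).
#' @param qual list of integer vectors, one per read, each the same length as
#'   its sequence, phred scale in \[0, 60\].
#' @return an object of class `read_set`.
#' @export
read_set <- function(id, seq, qual) {
  stopifnot(length(id) == length(seq), length(seq) == length(qual))
  if (anyDuplicated(id)) stop("read identifiers must be unique")
  ok <- mapply(function(s, q) nchar(s) == length(q), seq, qual)
  if (!all(ok)) stop("quality vector length must equal sequence length")
  structure(list(id = as.character(id), seq = toupper(as.character(seq)),
                 qual = lapply(qual, as.integer)),
            class = "read_set")
}

#' @export
length.read_set <- function(x) length(x$id)

#' @export
`[.read_set` <- function(x, i) {
  if (is.character(i)) i <- match(i, x$id)
  structure(list(id = x$id[i], seq = x$seq[i], qual = x$qual[i]),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set with %d reads (mean length %.1f bp)\n",
              length(x), if (length(x)) mean(nchar(x$seq)) else NA_real_))
  invisible(x)
}

#' Read a FASTQ file into a read set
#'
#' Phred+33 (Sanger) quality encoding throughout.
#'
#' @param path FASTQ file path.
#' @return a [read_set()].
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  qual <- lapply(as.character(S4Vectors::mcols(x)$qualities),
                 function(q) utf8ToInt(q) - 33L)
  read_set(names(x), as.character(x), qual)
}

#' Write a read set to FASTQ (phred+33)
#'
#' @param reads a [read_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  q <- Biostrings::BStringSet(vapply(reads$qual,
                                     function(v) intToUtf8(v + 33L), ""))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Write named sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  stats::setNames(as.character(x), names(x))
}
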