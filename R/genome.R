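#' Load a reference genome as a named character vector
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()]; the package works on
#' plain upper-case character strings internally because sequence surgery on
#' ~1 Mb windows (substring, concatenation) is fastest that way.
#'
#' @param path FASTA file.
#' @return Named character vector, one element per contig.
#' @export
load_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  # drop FASTA description after first whitespace
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Reverse complement of a plain character DNA string
#'
#' @param x single character string over the alphabet A, C, G, T, N.
#' @return Character string.
#' @export
revcomp <- function(x) {
  as.character(revcomp_cpp(x))
}

# substring by 0-based half-open genomic coordinates (byte-level: avoids
# R's locale-aware substr, which is O(position) on multi-megabase strings)
subseq0 <- function(contig_seq, start0, end0) {
  as.character(subseq_cpp(contig_seq, start0, end0))
}

# byte length of a sequence string, O(1)
slen <- function(x) as.integer(seq_len_cpp(x))

#' Write contigs to FASTA
#'
#' @param seqs named character vector of contig sequences.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}
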