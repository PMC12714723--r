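#' @import methods
#' @importFrom stats median runif setNames
#' @importFrom utils adist read.table write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 1 && nchar(x) < 500) {
    # fast scalar path for short sequences
    return(chartr("ACGTNacgtn", "TGCANtgcan",
                  paste(rev(strsplit(x, NULL)[[1]]), collapse = "")))
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random DNA sequence at a given GC content
#'
#' Bases are drawn i.i.d. with P(G) = P(C) = gc/2 and P(A) = P(T) = (1-gc)/2.
#' Uses the current RNG state; callers control reproducibility with set.seed.
#'
#' @param length sequence length in bp.
#' @param gc GC fraction in \[0, 1\].
#' @return a single DNA string.
#' @export
random_dna <- function(length, gc = 0.5) {
  stopifnot(length >= 0, gc >= 0, gc <= 1)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, length, replace = TRUE, prob = p), collapse = "")
}

# Substitute exactly n random positions with a different base.
mutate_substitutions <- function(seq, n) {
  if (n == 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  stopifnot(n <= length(ch))
  pos <- sample.int(length(ch), n)
  for (p in pos) {
    ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1)
  }
  paste(ch, collapse = "")
}

# Apply i.i.d. substitution errors at a per-base rate to a character vector.
apply_substitution_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  out <- vapply(seqs, function(s) {
    n <- nchar(s)
    k <- stats::rbinom(1, n, rate)
    if (k == 0) s else mutate_substitutions(s, k)
  }, character(1), USE.NAMES = FALSE)
  names(out) <- names(seqs)
  out
}

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(charToRaw(a) != charToRaw(b))
}

#' Write reads as FASTQ (Phred+33)
#'
#' @param reads named character vector of read sequences.
#' @param path output file path.
#' @param quality_char single character used as the constant base quality
#'   (default `"?"`, Q30).
#' @return invisibly, the path.
#' @export
write_fastq <- function(reads, path, quality_char = "?") {
  stopifnot(!is.null(names(reads)))
  dss <- Biostrings::DNAStringSet(unname(reads))
  names(dss) <- names(reads)
  quals <- Biostrings::BStringSet(strrep(quality_char, nchar(reads)))
  Biostrings::writeXStringSet(dss, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Read FASTQ into a named character vector
#'
#' @param path FASTQ file path.
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  dss <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(dss), names(dss))
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  dss <- Biostrings::DNAStringSet(unname(seqs))
  names(dss) <- names(seqs)
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Read FASTA into a named character vector
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(dss), names(dss))
}

# sample() without the scalar-x surprise: always samples from the elements
# of x, even when length(x) == 1.
sample1 <- function(x, size = 1, prob = NULL) {
  x[sample.int(length(x), size, replace = TRUE, prob = prob)]
}

# Round half away from zero to `digits` decimals (printed-table convention;
# base round() is half-to-even).
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# 0-based half-open substring of a 1-indexed R string.
substr0 <- function(x, start0, end0) {
  substr(x, start0 + 1L, end0)
}
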