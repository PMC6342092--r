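#' @importFrom Biostrings DNAStringSet reverseComplement IUPAC_CODE_MAP
#' @importFrom Rcpp evalCpp
#' @importFrom stats rbinom rmultinom rnorm runif lm coef t.test cor.test
#'   pt setNames
#' @importFrom utils adist read.delim write.table head
#' @useDynLib dietbarcoder, .registration = TRUE
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of character sequences
#'
#' IUPAC-aware reverse complement (so degenerate primer patterns can be
#' matched on the 3' end of a read in their sequenced orientation).
#'
#' @param x character vector of nucleotide/IUPAC strings.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

#' Convert between Phred scores and Phred+33 quality strings
#'
#' @param scores integer vector of Phred scores in \[0, 93\].
#' @return `phred_to_string()`: a single quality string; `string_to_phred()`:
#'   an integer vector of scores.
#' @export
phred_to_string <- function(scores) {
  stopifnot(all(scores >= 0L & scores <= 93L))
  intToUtf8(as.integer(scores) + 33L)
}

#' @rdname phred_to_string
#' @param qual a single Phred+33 encoded quality string.
#' @export
string_to_phred <- function(qual) {
  utf8ToInt(qual) - 33L
}

## mean Phred score per read, vectorised over quality strings
mean_phred <- function(quals) {
  vapply(quals, function(q) mean(utf8ToInt(q)) - 33, numeric(1), USE.NAMES = FALSE)
}

## deterministic random DNA string(s) under the current RNG state
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  }, character(1))
}

## substitute the base at `pos` with a different uniformly-chosen base
mutate_positions <- function(seq, pos) {
  if (length(pos) == 0L) return(seq)
  chars <- strsplit(seq, "")[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

## resolve IUPAC degenerate symbols to concrete bases (random choice per symbol)
resolve_iupac <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  out <- vapply(chars, function(ch) {
    opts <- strsplit(IUPAC_CODE_MAP[[ch]], "")[[1]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1), USE.NAMES = FALSE)
  paste(out, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
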