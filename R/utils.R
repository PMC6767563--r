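# Internal helpers shared across modules.
#
# All genomic coordinates inside the package are 0-based half-open; GFF3 is
# converted at the I/O boundary (1-based inclusive on disk).

DNA_BASES <- c("A", "C", "G", "T")

#' Streptomyces-like mononucleotide background (72% GC)
#' @keywords internal
default_background <- function(gc = 0.72) {
  stats::setNames(c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2), DNA_BASES)
}

# Encode a DNA string as integers 1..4 (A,C,G,T); N and other letters -> NA.
encode_dna <- function(x) {
  v <- match(strsplit(toupper(x), "", fixed = TRUE)[[1]], DNA_BASES)
  v
}

decode_dna <- function(v) paste(DNA_BASES[v], collapse = "")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Draw n i.i.d. bases at the given background frequencies.
random_dna <- function(n, background = default_background()) {
  paste(sample(DNA_BASES, n, replace = TRUE, prob = background[DNA_BASES]),
        collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Empirical mononucleotide frequencies of a character vector of sequences,
# ignoring non-ACGT letters.
mono_frequencies <- function(seqs) {
  tab <- table(factor(unlist(strsplit(toupper(paste(seqs, collapse = "")), "",
                                      fixed = TRUE)),
                      levels = DNA_BASES))
  n <- sum(tab)
  if (n == 0L) return(default_background())
  stats::setNames(as.numeric(tab) / n, DNA_BASES)
}
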