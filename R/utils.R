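# Small sequence helpers shared across modules. Biostrings does the heavy
# lifting; these wrappers keep the rest of the package working on plain
# character vectors.

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (ACGT).
#' @return Character vector of reverse complements, names preserved.
#' @export
revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  out
}

#' Translate DNA to amino acids
#'
#' Translates in frame 1 with the standard genetic code; trailing bases that
#' do not complete a codon are dropped. Stop codons appear as `*`.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of amino-acid sequences.
#' @export
translate_dna <- function(x) {
  x <- toupper(x)
  n <- nchar(x) %/% 3L * 3L
  x <- substr(x, 1L, n)
  empty <- n == 0L
  out <- character(length(x))
  if (any(!empty)) {
    out[!empty] <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(x[!empty])
    ))
  }
  names(out) <- names(x)
  out
}

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming(): sequences differ in length")
  sum(charToRaw(a) != charToRaw(b))
}

# Half-up rounding (0.05 rounds to 0.1), as used for printed usage
# percentages. Base round() rounds half to even. A tiny epsilon guards
# against values such as 24.2499999... produced by binary floating point.
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

# Uniform random DNA of length n (uses the current RNG stream).
random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Longest common prefix / suffix length of two strings.
common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  ra <- charToRaw(substr(a, 1L, n)); rb <- charToRaw(substr(b, 1L, n))
  d <- which(ra != rb)
  if (length(d) == 0L) n else d[1L] - 1L
}

common_suffix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  ra <- rev(charToRaw(substr(a, nchar(a) - n + 1L, nchar(a))))
  rb <- rev(charToRaw(substr(b, nchar(b) - n + 1L, nchar(b))))
  d <- which(ra != rb)
  if (length(d) == 0L) n else d[1L] - 1L
}

# All length-k substrings of a string (character vector, possibly empty).
kmers <- function(x, k) {
  L <- nchar(x)
  if (L < k) return(character(0))
  substring(x, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
}
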