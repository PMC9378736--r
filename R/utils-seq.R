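#' Nucleotide sequence helpers
#'
#' Small vectorised utilities used across the simulator and the detector.
#' Sequences are plain upper-case character strings over the ACGT alphabet;
#' coordinates are 0-based half-open throughout the package.
#'
#' @param x Character vector of nucleotide sequences.
#' @return `revcomp()` returns the reverse complement of each sequence.
#' @examples
#' revcomp("ACGTT")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  chartr("ACGTacgt", "TGCAtgca", x) |>
    vapply(function(s) {
      paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
}

# 0-based half-open substring: sub0(s, a, b) == s[a, b)
sub0 <- function(s, start, end) substring(s, start + 1L, end)

# Hamming distance between two equal-length strings (fast byte compare).
hamming <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  if (length(ra) != length(rb)) return(Inf)
  sum(ra != rb)
}

# Per-position mismatch logical vector between equal-length strings.
mismatch_vec <- function(a, b) charToRaw(a) != charToRaw(b)

# Sample a random DNA string with a given GC fraction.
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Replace s[start, end) (0-based half-open) with `value`.
splice_into <- function(s, start, value) {
  stopifnot(start >= 0, start + nchar(value) <= nchar(s))
  paste0(sub0(s, 0L, start), value, sub0(s, start + nchar(value), nchar(s)))
}

# Translate a nucleotide string (length divisible by 3) to amino acids using
# the standard genetic code; codons with non-ACGT characters give "X".
translate_nt <- function(nt) {
  if (nchar(nt) == 0L) return("")
  codons <- substring(nt, seq(1L, nchar(nt), by = 3L),
                      seq(3L, nchar(nt), by = 3L))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s].",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}
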