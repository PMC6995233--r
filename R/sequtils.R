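DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N, case-insensitive).
#' @return character vector of reverse complements, uppercase.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s)
    intToUtf8(rev(utf8ToInt(chartr("ACGTNacgtn", "TGCANTGCAN", s)))),
    "", USE.NAMES = FALSE)
}

#' Validate a DNA string
#'
#' Ambiguity codes other than N are rejected: unreadable genome segments are
#' represented as runs of N, and nothing else is accepted.
#' @param x single DNA string.
#' @param what label used in error messages.
#' @return the uppercased string, invisibly usable.
#' @export
check_dna <- function(x, what = "sequence") {
  stopifnot(is.character(x), length(x) == 1)
  x <- toupper(x)
  if (nchar(x) == 0) stop(what, " is empty")
  if (grepl("[^ACGTN]", x)) {
    stop(what, " contains characters outside A/C/G/T/N ",
         "(ambiguity codes beyond N are not supported)")
  }
  x
}

#' Translate DNA to protein (standard genetic code)
#'
#' @param dna in-frame DNA string; trailing partial codon is dropped.
#' @return single protein string; stop codons appear as `*`.
#' @export
translate_dna <- function(dna) {
  dna <- toupper(dna)
  n <- nchar(dna) %/% 3L
  if (n == 0) return("")
  codons <- substring(dna, seq(1, by = 3, length.out = n),
                      seq(3, by = 3, length.out = n))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"  # codons containing N
  paste(aa, collapse = "")
}

# round half away from zero at `digits` decimals; R's round() is half-even,
# which does not reproduce the one-decimal table convention used here
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

# uniform random DNA of length n (requires an initialized RNG)
random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# guess molecule type from the residue alphabet
guess_moltype <- function(x) {
  x <- toupper(x)
  if (!grepl("[^ACGTN]", x)) "dna" else "protein"
}
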