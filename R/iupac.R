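#' IUPAC nucleotide ambiguity classes
#'
#' Named list mapping each IUPAC code to the set of concrete bases it
#' stands for (e.g. R = A/G, N = A/C/G/T).
#'
#' @keywords internal
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

#' Test a sequence window against an IUPAC PAM pattern
#'
#' Position-wise comparison of an uppercase ACGTN window against an IUPAC
#' pattern of the same length. A pattern position matches when the subject
#' base belongs to that code's base set. An 'N' in the *subject* is an
#' unknown base: it fails every pattern position except a pattern 'N'
#' (conservative site calling).
#'
#' @param sequenceWindow Single uppercase ACGTN string.
#' @param pattern IUPAC pattern string of the same length.
#' @return `TRUE` iff every position matches.
#' @examples
#' matchesPam("TGG", "NGG")      # TRUE
#' matchesPam("TTTA", "TTTN")    # TRUE
#' matchesPam("AAGACT", "NNGRRT") # FALSE (C is not R)
#' @export
matchesPam <- function(sequenceWindow, pattern) {
  stopifnot(is.character(sequenceWindow), length(sequenceWindow) == 1L,
            is.character(pattern), length(pattern) == 1L)
  if (nchar(sequenceWindow) != nchar(pattern))
    stop(sprintf("window length (%d) != pattern length (%d)",
                 nchar(sequenceWindow), nchar(pattern)))
  iupacMatchMany(sequenceWindow, pattern)
}

# Vectorised core: windows is a character vector, all nchar == nchar(pattern).
# Subject 'N' only matches pattern 'N'.
iupacMatchMany <- function(windows, pattern) {
  pchars <- strsplit(pattern, "")[[1]]
  bad <- !pchars %in% names(IUPAC_SETS)
  if (any(bad))
    stop(sprintf("non-IUPAC character(s) in pattern '%s': %s", pattern,
                 paste(unique(pchars[bad]), collapse = ", ")))
  ok <- rep(TRUE, length(windows))
  for (j in seq_along(pchars)) {
    allowed <- IUPAC_SETS[[pchars[j]]]
    if (pchars[j] == "N") allowed <- c(allowed, "N")
    ok <- ok & substr(windows, j, j) %in% allowed
    if (!any(ok)) break
  }
  ok
}

# Reverse complement for plain character vectors (IUPAC-aware).
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Sample a concrete ACGT realisation of an IUPAC pattern (used by the
# simulator to embed PAMs). Uses the current RNG stream.
realizeIupac <- function(pattern) {
  pchars <- strsplit(pattern, "")[[1]]
  paste(vapply(pchars, function(p) {
    s <- IUPAC_SETS[[p]]
    if (length(s) == 1L) s else sample(s, 1L)
  }, character(1)), collapse = "")
}
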