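# IUPAC nucleotide codes as 4-bit sets over (A, C, G, T). Two codes are
# compatible iff their bit sets intersect; a primer/template position is a
# mismatch iff the intersection is empty. U is treated as T throughout.
.IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
  M = 3L, R = 5L, W = 9L, S = 6L, Y = 10L, K = 12L,
  V = 7L, H = 11L, D = 13L, B = 14L, N = 15L
)

# bit-set -> canonical single-letter code (index = bit value)
.BITS_TO_CODE <- c("A", "C", "M", "G", "R", "S", "V",
                   "T", "W", "Y", "H", "K", "D", "B", "N")

#' Bases denoted by an IUPAC nucleotide code
#'
#' @param code Single IUPAC nucleotide letter (case-insensitive; `U` is an
#'   alias for `T`).
#' @return Character vector of the unambiguous bases (subset of A, C, G, T)
#'   the code stands for.
#' @examples
#' iupac_bases("S")  # C, G
#' @export
iupac_bases <- function(code) {
  bits <- .IUPAC_BITS[toupper(code)]
  if (length(bits) != 1L || is.na(bits)) {
    stop("not an IUPAC nucleotide code: '", code, "'")
  }
  c("A", "C", "G", "T")[bitwAnd(bits, c(1L, 2L, 4L, 8L)) > 0L]
}

#' Minimal IUPAC code covering a set of bases
#'
#' @param bases Character vector drawn from A, C, G, T (case-insensitive).
#' @return Single IUPAC letter whose base set is exactly `union(bases)`.
#' @export
iupac_code_for <- function(bases) {
  bits <- .IUPAC_BITS[toupper(bases)]
  if (anyNA(bits) || any(!toupper(bases) %in% c("A", "C", "G", "T"))) {
    stop("bases must be drawn from A, C, G, T")
  }
  .BITS_TO_CODE[Reduce(bitwOr, bits, accumulate = FALSE)]
}

# Encode a nucleotide string as an integer vector of IUPAC bit sets.
# Unknown characters encode to 0 (the empty set), so they mismatch everything;
# callers that must reject them outright validate first.
.encode_iupac <- function(x) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  bits <- unname(.IUPAC_BITS[chars])
  bits[is.na(bits)] <- 0L
  bits
}

# Positions (if any) holding characters outside the IUPAC alphabet.
.invalid_iupac_positions <- function(x) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  which(!chars %in% names(.IUPAC_BITS))
}

#' Reverse complement of an IUPAC nucleotide string
#'
#' Complements every IUPAC code set-wise (e.g. `R` = A/G becomes `Y` = C/T)
#' and reverses the string. `U` complements to `A`.
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTUMRWSYKVHDBNacgtumrwsykvhdbn",
                 "TGCAAKYWSRMBDHVNtgcaakywsrmbdhvn", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Count IUPAC mismatches between a primer and an equal-length window
#'
#' A position counts as a mismatch iff the IUPAC base sets of the two
#' characters do not intersect. The comparison is ungapped: no indels are
#' considered. A template `N` therefore never adds a mismatch.
#'
#' @param primer Primer sequence (IUPAC string, 5'→3').
#' @param window Template window of the same length.
#' @return Integer mismatch count.
#' @examples
#' iupac_mismatches("ACGS", "ACGC")  # 0: S covers C
#' iupac_mismatches("ACGS", "ACGA")  # 1
#' @export
iupac_mismatches <- function(primer, window) {
  if (nchar(primer) != nchar(window)) {
    stop("primer and window lengths differ (", nchar(primer),
         " vs ", nchar(window), ")")
  }
  sum(bitwAnd(.encode_iupac(primer), .encode_iupac(window)) == 0L)
}
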