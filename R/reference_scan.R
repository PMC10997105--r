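# Independent reference implementation of the binding-site scan and the
# amplification step, built on Biostrings::matchPattern with fixed = FALSE
# (IUPAC set-intersection matching). It shares no code with the engine in
# insilico_pcr.R and is used two ways: as the oracle in equivalence tests,
# and by the synthetic-data generator to certify that generated instances
# contain exactly the planted hits.

#' Reference binding-site scan (Biostrings)
#'
#' All-windows scan via [Biostrings::matchPattern()] with IUPAC
#' set-intersection semantics. Exact mismatch counts are recovered by
#' stepping the mismatch allowance 0..`max_mismatches`.
#'
#' @inheritParams find_binding_sites
#' @return Data frame `start, end, mismatches` (0-based half-open), ascending
#'   start order.
#' @export
oracle_find_sites <- function(sequence, primer, max_mismatches) {
  subject <- Biostrings::DNAString(sequence)
  pat <- Biostrings::DNAString(primer)
  starts <- integer(0)
  mism <- integer(0)
  seen <- integer(0)
  for (k in 0:max_mismatches) {
    m <- Biostrings::matchPattern(pat, subject, max.mismatch = k,
                                  fixed = FALSE)
    st <- BiocGenerics::start(m)
    new <- setdiff(st, seen)
    starts <- c(starts, new)
    mism <- c(mism, rep(k, length(new)))
    seen <- c(seen, new)
  }
  ord <- order(starts)
  data.frame(start = starts[ord] - 1L,
             end = starts[ord] - 1L + nchar(primer),
             mismatches = mism[ord])
}

#' Reference amplification (all-pairs brute force)
#'
#' Pairs every forward site with every downstream reverse-complement site on
#' each strand and keeps pairs whose inter-primer distance lies within the
#' primer pair's bounds.
#'
#' @inheritParams amplify
#' @return Data frame `strand, fwd_start, fwd_end, rev_start, rev_end,
#'   mm_fwd, mm_rev, amplicon_len, metabarcode` with forward-strand 0-based
#'   half-open coordinates, same conventions as [amplify()].
#' @export
oracle_amplify <- function(sequence, pair, max_mismatches = 3L) {
  n <- nchar(sequence)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") sequence else revcomp(sequence)
    f <- oracle_find_sites(s, pair$forward, max_mismatches)
    r <- oracle_find_sites(s, revcomp(pair$reverse), max_mismatches)
    for (i in seq_len(nrow(f))) {
      for (j in seq_len(nrow(r))) {
        len <- r$start[j] - f$end[i]
        if (len < pair$min_len || len > pair$max_len) next
        mb <- substring(s, f$end[i] + 1L, r$start[j])
        if (strand == "+") {
          coords <- c(f$start[i], f$end[i], r$start[j], r$end[j])
        } else {
          coords <- c(n - f$end[i], n - f$start[i],
                      n - r$end[j], n - r$start[j])
        }
        rows[[length(rows) + 1L]] <- data.frame(
          strand = strand, fwd_start = coords[1], fwd_end = coords[2],
          rev_start = coords[3], rev_end = coords[4],
          mm_fwd = f$mismatches[i], mm_rev = r$mismatches[j],
          amplicon_len = len, metabarcode = mb, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(strand = character(0), fwd_start = integer(0),
                      fwd_end = integer(0), rev_start = integer(0),
                      rev_end = integer(0), mm_fwd = integer(0),
                      mm_rev = integer(0), amplicon_len = integer(0),
                      metabarcode = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$strand, out$fwd_start, out$rev_start), , drop = FALSE]
}
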