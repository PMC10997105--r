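# Per-position conservation of primer-matching regions, the quantitative
# content of a sequence logo: nucleotide frequencies and information content
# info = 2 - H, with H the base-2 Shannon entropy, so 0 bits means the four
# nucleotides are equally likely and 2 bits means perfect conservation.

# scanned-strand view of a record and of a designated hit's coordinates
.scanned_coords <- function(hit, seq_len) {
  if (hit$strand == "+") {
    list(fs = hit$fwd_start, fe = hit$fwd_end,
         rs = hit$rev_start, re = hit$rev_end)
  } else {
    list(fs = seq_len - hit$fwd_end, fe = seq_len - hit$fwd_start,
         rs = seq_len - hit$rev_end, re = seq_len - hit$rev_start)
  }
}

#' Collect template windows under a primer footprint
#'
#' For every designated hit (optionally after one-per-species deduplication,
#' the convention used for logo building), extracts the template region under
#' the chosen primer's footprint, oriented 5'→3' as that primer reads it.
#' With `flank > 0` the window is extended by `flank` bases on both sides;
#' hits whose template does not extend far enough are dropped.
#'
#' @param result An `amplification_result`.
#' @param records The reference data frame the result came from.
#' @param side `"forward"` or `"reverse"`.
#' @param flank Non-negative flank width in bp.
#' @param dedup Apply [dedup_one_per_species()] first?
#' @param seed Dedup seed (recorded in run manifests).
#' @return Character vector of equal-length windows.
#' @export
collect_primer_windows <- function(result, records,
                                   side = c("forward", "reverse"),
                                   flank = 0L, dedup = FALSE, seed = 101L) {
  stopifnot(inherits(result, "amplification_result"))
  side <- match.arg(side)
  flank <- as.integer(flank)
  stopifnot(flank >= 0L)
  if (dedup) records <- dedup_one_per_species(records, seed)
  des <- result$designated
  des <- des[des$record_id %in% records$record_id, , drop = FALSE]
  if (nrow(des) == 0L) return(character(0))
  rownames(records) <- records$record_id

  out <- character(0)
  for (i in seq_len(nrow(des))) {
    hit <- des[i, ]
    seq <- records[hit$record_id, "sequence"]
    n <- nchar(seq)
    scanned <- if (hit$strand == "+") seq else revcomp(seq)
    co <- .scanned_coords(hit, n)
    if (side == "forward") {
      lo <- co$fs - flank
      hi <- co$fe + flank
      if (lo < 0L || hi > n) next
      out <- c(out, substring(scanned, lo + 1L, hi))
    } else {
      # the reverse primer reads the opposite strand of the scanned one
      lo <- co$rs - flank
      hi <- co$re + flank
      if (lo < 0L || hi > n) next
      out <- c(out, revcomp(substring(scanned, lo + 1L, hi)))
    }
  }
  out
}

#' Per-position conservation matrix
#'
#' Nucleotide frequencies and information content for an aligned set of
#' equal-length windows. Template ambiguity codes (anything outside A, C, G,
#' T) are dropped from that position's count. No small-sample correction is
#' applied, matching the stated 0–2 bit range; `small_sample_correction =
#' TRUE` subtracts the classic e(n) correction for rendering parity with
#' logo tools.
#'
#' @param windows Character vector of equal-length nucleotide windows.
#' @param small_sample_correction Apply the e(n) correction?
#' @return Object of class `conservation_matrix`: list with `freq` (L x 4
#'   matrix of probabilities over A, C, G, T), `info` (bits per position),
#'   `counts` and `n_sequences`.
#' @export
conservation_matrix <- function(windows, small_sample_correction = FALSE) {
  if (length(windows) == 0L) stop("empty window set")
  lens <- nchar(windows)
  if (length(unique(lens)) != 1L) stop("windows must have equal lengths")
  L <- lens[1]
  mat <- do.call(rbind, strsplit(toupper(windows), "", fixed = TRUE))
  bases <- c("A", "C", "G", "T")
  counts <- vapply(seq_len(L), function(i) {
    col <- mat[, i]
    vapply(bases, function(b) sum(col == b), numeric(1))
  }, numeric(4))
  counts <- t(counts)  # L x 4
  colnames(counts) <- bases
  totals <- rowSums(counts)
  freq <- counts / ifelse(totals == 0, NA_real_, totals)
  H <- apply(freq, 1, function(p) {
    if (all(is.na(p))) return(NA_real_)  # position with only ambiguity codes
    p <- p[!is.na(p) & p > 0]
    -sum(p * log2(p))
  })
  info <- 2 - H
  if (small_sample_correction) {
    info <- pmax(0, info - 3 / (2 * log(2) * length(windows)))
  }
  structure(list(freq = freq, info = unname(info), counts = counts,
                 n_sequences = length(windows)),
            class = "conservation_matrix")
}

#' @export
print.conservation_matrix <- function(x, ...) {
  cat(sprintf("<conservation_matrix> %d positions, %d sequences, info %.2f-%.2f bits\n",
              nrow(x$freq), x$n_sequences, min(x$info), max(x$info)))
  invisible(x)
}

#' @export
as.data.frame.conservation_matrix <- function(x, ...) {
  data.frame(position = seq_len(nrow(x$freq)),
             A = x$freq[, "A"], C = x$freq[, "C"],
             G = x$freq[, "G"], T = x$freq[, "T"],
             bits = x$info, n = x$n_sequences)
}

#' Write a conservation matrix as TSV
#'
#' @param x A `conservation_matrix`.
#' @param path Output path; columns `position, A, C, G, T, bits, n`.
#' @export
write_conservation_table <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
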