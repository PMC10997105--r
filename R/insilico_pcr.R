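# The amplification model. A primer pair amplifies a template when a
# forward-primer binding site and, downstream of it, a site matching the
# reverse complement of the reverse primer are both found within the mismatch
# budget, and the inter-primer distance (the metabarcode, excluding both
# primer footprints) lies within the pair's length bounds. Both strands are
# scanned; the minus strand is handled by scanning the reverse complement.
# Coordinates are 0-based half-open on the forward strand of the stored
# sequence; human-facing reports are 1-based inclusive.

.empty_hits <- function() {
  data.frame(record_id = character(0), strand = character(0),
             fwd_start = integer(0), fwd_end = integer(0),
             rev_start = integer(0), rev_end = integer(0),
             mm_fwd = integer(0), mm_rev = integer(0),
             amplicon_len = integer(0), metabarcode = character(0),
             fwd_window = character(0), rev_window = character(0),
             stringsAsFactors = FALSE)
}

#' Find primer binding sites in a sequence
#'
#' Slides the primer along the template (ungapped) and reports every window
#' whose IUPAC-set mismatch count (see [iupac_mismatches()]) is within the
#' budget. Template ambiguity codes match whenever the base sets intersect,
#' so a template `N` never contributes a mismatch.
#'
#' @param sequence Template sequence (IUPAC string).
#' @param primer Primer sequence, 5'→3'.
#' @param max_mismatches Maximum mismatches tolerated.
#' @return Data frame `start, end, mismatches` (0-based half-open), in
#'   ascending start order; zero rows when no site qualifies.
#' @export
find_binding_sites <- function(sequence, primer, max_mismatches) {
  m <- nchar(primer)
  n <- nchar(sequence)
  empty <- data.frame(start = integer(0), end = integer(0),
                      mismatches = integer(0))
  if (m > n) return(empty)
  s <- .encode_iupac(sequence)
  p <- .encode_iupac(primer)
  nw <- n - m + 1L
  counts <- integer(nw)
  for (j in seq_len(m)) {
    counts <- counts + (bitwAnd(p[j], s[j:(nw + j - 1L)]) == 0L)
  }
  hit <- which(counts <= max_mismatches)
  data.frame(start = hit - 1L, end = hit - 1L + m,
             mismatches = counts[hit])
}

# Scan one strand: returns hits with coordinates on the scanned strand plus
# the scanned-strand windows and metabarcode. `seq` is the scanned strand.
.scan_strand <- function(seq, pair, max_mismatches) {
  f_sites <- find_binding_sites(seq, pair$forward, max_mismatches)
  if (nrow(f_sites) == 0L) return(NULL)
  r_sites <- find_binding_sites(seq, revcomp(pair$reverse), max_mismatches)
  if (nrow(r_sites) == 0L) return(NULL)
  combos <- expand.grid(fi = seq_len(nrow(f_sites)),
                        ri = seq_len(nrow(r_sites)))
  len <- r_sites$start[combos$ri] - f_sites$end[combos$fi]
  ok <- len >= pair$min_len & len <= pair$max_len
  if (!any(ok)) return(NULL)
  combos <- combos[ok, , drop = FALSE]
  len <- len[ok]
  data.frame(
    sf_start = f_sites$start[combos$fi], sf_end = f_sites$end[combos$fi],
    sr_start = r_sites$start[combos$ri], sr_end = r_sites$end[combos$ri],
    mm_fwd = f_sites$mismatches[combos$fi],
    mm_rev = r_sites$mismatches[combos$ri],
    amplicon_len = len,
    metabarcode = substring(seq, f_sites$end[combos$fi] + 1L,
                            r_sites$start[combos$ri]),
    fwd_window = substring(seq, f_sites$start[combos$fi] + 1L,
                           f_sites$end[combos$fi]),
    rev_window = revcomp(substring(seq, r_sites$start[combos$ri] + 1L,
                                   r_sites$end[combos$ri])),
    stringsAsFactors = FALSE
  )
}

#' Amplify one template with a primer pair
#'
#' Enumerates all valid binding-site pairs on both strands. The metabarcode
#' is the inter-primer region, excluding both primer footprints, oriented
#' 5'→3' relative to the forward primer. `fwd_window`/`rev_window` are the
#' template regions under the two footprints, each oriented as its primer
#' reads it.
#'
#' @param sequence Template sequence, or a one-row reference data frame.
#' @param pair A [primer_pair()].
#' @param max_mismatches Per-primer mismatch budget (default 3: the budget
#'   applies to the forward and the reverse primer separately, not summed).
#' @param record_id Id used in the output (taken from the data frame if one
#'   is supplied).
#' @return Data frame of amplicon hits, possibly empty. Coordinates are
#'   0-based half-open on the forward strand of the stored sequence.
#' @export
amplify <- function(sequence, pair, max_mismatches = 3L, record_id = "") {
  if (is.data.frame(sequence)) {
    record_id <- sequence$record_id[1]
    sequence <- sequence$sequence[1]
  }
  stopifnot(inherits(pair, "primer_pair"), max_mismatches >= 0L)
  n <- nchar(sequence)
  out <- .empty_hits()

  plus <- .scan_strand(sequence, pair, max_mismatches)
  if (!is.null(plus)) {
    out <- rbind(out, data.frame(
      record_id = record_id, strand = "+",
      fwd_start = plus$sf_start, fwd_end = plus$sf_end,
      rev_start = plus$sr_start, rev_end = plus$sr_end,
      mm_fwd = plus$mm_fwd, mm_rev = plus$mm_rev,
      amplicon_len = plus$amplicon_len, metabarcode = plus$metabarcode,
      fwd_window = plus$fwd_window, rev_window = plus$rev_window,
      stringsAsFactors = FALSE))
  }
  minus <- .scan_strand(revcomp(sequence), pair, max_mismatches)
  if (!is.null(minus)) {
    # map scanned-strand coordinates back onto the forward strand
    out <- rbind(out, data.frame(
      record_id = record_id, strand = "-",
      fwd_start = n - minus$sf_end, fwd_end = n - minus$sf_start,
      rev_start = n - minus$sr_end, rev_end = n - minus$sr_start,
      mm_fwd = minus$mm_fwd, mm_rev = minus$mm_rev,
      amplicon_len = minus$amplicon_len, metabarcode = minus$metabarcode,
      fwd_window = minus$fwd_window, rev_window = minus$rev_window,
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

# Designate one hit per record for metric use: shortest amplicon, ties broken
# by smallest fwd_start, then strand + before -. Mimics preferential
# amplification of shorter fragments and is deterministic.
.designate_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$record_id, hits$amplicon_len, hits$fwd_start,
               hits$strand == "-")
  hits <- hits[ord, , drop = FALSE]
  hits <- hits[!duplicated(hits$record_id), , drop = FALSE]
  hits[order(match(hits$record_id, unique(hits$record_id))), , drop = FALSE]
}

#' Amplify every record of a reference database
#'
#' @param records Reference data frame.
#' @param pair A [primer_pair()].
#' @param max_mismatches Per-primer mismatch budget (default 3).
#' @return Object of class `amplification_result`: a list with `hits` (all
#'   hits, all records), `designated` (one hit per amplified record — the
#'   shortest amplicon, deterministic tie-breaks), `amplified` (named logical
#'   per record), `n_total`, `primer` (the pair's name) and `pair`.
#' @export
amplify_db <- function(records, pair, max_mismatches = 3L) {
  hit_list <- lapply(seq_len(nrow(records)), function(i) {
    amplify(records$sequence[i], pair, max_mismatches,
            record_id = records$record_id[i])
  })
  hits <- do.call(rbind, c(list(.empty_hits()), hit_list))
  rownames(hits) <- NULL
  amplified <- setNames(records$record_id %in% hits$record_id,
                        records$record_id)
  structure(list(hits = hits, designated = .designate_hits(hits),
                 amplified = amplified, n_total = nrow(records),
                 primer = pair$name, pair = pair,
                 max_mismatches = as.integer(max_mismatches)),
            class = "amplification_result")
}

#' @export
print.amplification_result <- function(x, ...) {
  cat(sprintf("<amplification_result> %s: %d/%d records amplified (max %d mismatches per primer)\n",
              x$primer, sum(x$amplified), x$n_total, x$max_mismatches))
  invisible(x)
}

#' Write an amplicon table
#'
#' Human-facing report: coordinates converted to 1-based inclusive.
#'
#' @param result An `amplification_result`.
#' @param path Output TSV path.
#' @param designated_only Write only the designated hit per record?
#' @export
write_amplicon_table <- function(result, path, designated_only = FALSE) {
  h <- if (designated_only) result$designated else result$hits
  out <- data.frame(
    record_id = h$record_id, primer = result$primer, strand = h$strand,
    fwd_start = h$fwd_start + 1L, fwd_end = h$fwd_end,
    rev_start = h$rev_start + 1L, rev_end = h$rev_end,
    mm_fwd = h$mm_fwd, mm_rev = h$mm_rev,
    amplicon_len = h$amplicon_len, metabarcode = h$metabarcode,
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
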