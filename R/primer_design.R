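# Primer refinement scan: compare per-position variability of the
# primer-matching region (plus flanks) between target and non-target
# partitions, weight positions toward the 3' end, and propose shifted and/or
# re-specified primer variants that sit on the most discriminating positions.
# A good discriminator is conserved in the target and variable in the
# non-target partition: delta = non-target entropy - target entropy
# (= target info - non-target info), in bits, is largest there.

#' Per-position variability scan of target vs non-target primer regions
#'
#' Both window sets must be aligned to the same primer anchor and extended by
#' the same flank (see [collect_primer_windows()] with `flank`): each window
#' has length `L + 2 * flank` where `L` is the primer length. Positions are
#' numbered `1 - flank` to `L + flank`, with `1..L` the primer body.
#' The 3' weight rises linearly from `weight_range[1]` at the 5' end to
#' `weight_range[2]` at the 3' end; positions are ranked by weighted delta
#' (higher = better discriminator).
#'
#' @param target_windows,nontarget_windows Equal-length window sets for the
#'   two partitions.
#' @param flank Flank width the windows were extracted with.
#' @param weight_range Endpoints of the linear 3' weight ramp.
#' @param consensus_threshold Minimum target-partition base frequency for a
#'   base to enter the per-position consensus IUPAC code.
#' @return Object of class `variability_scan`: list with `table` (data frame
#'   `position, target_info, nontarget_info, delta, weight, weighted_delta,
#'   rank`), `flank`, `primer_len`, `consensus` (IUPAC code per scanned
#'   position) and `target_windows` (kept for coverage estimation in
#'   [propose_variants()]).
#' @export
variability_scan <- function(target_windows, nontarget_windows, flank = 10L,
                             weight_range = c(1, 3),
                             consensus_threshold = 0.05) {
  if (length(target_windows) == 0L) stop("target partition is empty")
  if (length(nontarget_windows) == 0L) stop("non-target partition is empty")
  W <- nchar(target_windows[1])
  if (any(nchar(c(target_windows, nontarget_windows)) != W)) {
    stop("all windows must share one length")
  }
  L <- W - 2L * flank
  if (L < 1L) stop("flank too large for window length ", W)

  cm_t <- conservation_matrix(target_windows)
  cm_n <- conservation_matrix(nontarget_windows)
  delta <- cm_t$info - cm_n$info  # = H_nontarget - H_target
  weight <- seq(weight_range[1], weight_range[2], length.out = W)
  wdelta <- delta * weight
  tab <- data.frame(
    position = seq_len(W) - flank,  # 1..L is the primer body
    target_info = cm_t$info,
    nontarget_info = cm_n$info,
    delta = delta,
    weight = weight,
    weighted_delta = wdelta
  )
  tab$rank <- rank(-tab$weighted_delta, ties.method = "first")

  consensus <- vapply(seq_len(W), function(i) {
    p <- cm_t$freq[i, ]
    keep <- !is.na(p) & p >= consensus_threshold
    if (!any(keep)) return("N")
    iupac_code_for(names(p)[keep])
  }, character(1))

  structure(list(table = tab, flank = as.integer(flank), primer_len = L,
                 consensus = consensus, target_windows = target_windows,
                 weight_range = weight_range),
            class = "variability_scan")
}

#' @export
print.variability_scan <- function(x, ...) {
  top <- x$table[x$table$rank == 1L, ]
  cat(sprintf("<variability_scan> primer body %d nt + %d nt flanks; top discriminator at position %d (weighted delta %.2f bits)\n",
              x$primer_len, x$flank, top$position, top$weighted_delta))
  invisible(x)
}

#' Write a variability scan as TSV
#'
#' @param scan A `variability_scan`.
#' @param path Output path.
#' @export
write_variability_scan <- function(scan, path) {
  write.table(scan$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# sequence of a candidate footprint: primer bases where the footprint overlaps
# the original body, target-consensus codes where it extends into a flank
.shifted_candidate <- function(scan, base_primer, shift) {
  L <- scan$primer_len
  body <- strsplit(base_primer, "", fixed = TRUE)[[1]]
  idx <- seq_len(L) + shift            # body positions covered, in 1..L space
  out <- character(L)
  inside <- idx >= 1L & idx <= L
  out[inside] <- body[idx[inside]]
  out[!inside] <- scan$consensus[idx[!inside] + scan$flank]
  out
}

#' Propose refined primer candidates from a variability scan
#'
#' Candidates are the base primer shifted along the template by up to
#' `max_shift` positions (new positions filled with the target-consensus
#' IUPAC code) and/or with up to `max_edits` positions re-specified to the
#' consensus code. Each candidate is scored by
#' `score = coverage_est + wdelta_norm`, where `coverage_est` is the fraction
#' of target windows the candidate matches within `max_mismatches`, and
#' `wdelta_norm` is the 3'-weighted delta summed over the candidate footprint,
#' normalized by a shift-independent bound (2 bits at every position at the
#' top weight) so both terms live on `[0, 1]`-type scales and, at equal
#' coverage, ranking is monotone in the weighted-delta sum. Ranking is deterministic: score
#' descending, then fewer edits, then lexicographic sequence order.
#'
#' @param scan A `variability_scan`.
#' @param base_primer The primer the scan is anchored on (length must equal
#'   `scan$primer_len`).
#' @param max_shift Maximum shift in bp (must not exceed the scan flank).
#' @param max_edits Maximum re-specified positions per candidate.
#' @param max_mismatches Mismatch budget used for the coverage estimate.
#' @return Data frame `primer_sequence, shift, edits, coverage_est,
#'   weighted_delta, score`, best candidate first.
#' @export
propose_variants <- function(scan, base_primer, max_shift = 0L,
                             max_edits = 0L, max_mismatches = 3L) {
  stopifnot(inherits(scan, "variability_scan"))
  if (nchar(base_primer) != scan$primer_len) {
    stop("base primer length ", nchar(base_primer),
         " does not match scan primer body ", scan$primer_len)
  }
  if (max_shift > scan$flank) stop("max_shift exceeds the scan flank")
  L <- scan$primer_len
  wd <- scan$table$weighted_delta
  # shift-independent normalizer (the maximum attainable footprint sum, 2
  # bits at every position at the top weight), so that at equal coverage the
  # ranking is strictly monotone in the weighted-delta sum
  wnorm <- 2 * L * scan$weight_range[2]

  cands <- list()
  for (shift in seq(-max_shift, max_shift)) {
    chars0 <- .shifted_candidate(scan, base_primer, shift)
    foot <- seq_len(L) + shift + scan$flank  # rows of scan$table covered
    editable <- which(chars0 != scan$consensus[foot])
    edit_sets <- list(integer(0))
    if (max_edits > 0L && length(editable) > 0L) {
      for (k in seq_len(min(max_edits, length(editable)))) {
        sets <- utils::combn(editable, k, simplify = FALSE)
        edit_sets <- c(edit_sets, sets)
      }
    }
    for (es in edit_sets) {
      chars <- chars0
      chars[es] <- scan$consensus[foot[es]]
      seqc <- paste(chars, collapse = "")
      cov <- mean(vapply(scan$target_windows, function(w) {
        iupac_mismatches(seqc, substring(w, foot[1], foot[L])) <=
          max_mismatches
      }, logical(1)))
      wsum <- sum(wd[foot])
      cands[[length(cands) + 1L]] <- data.frame(
        primer_sequence = seqc, shift = shift, edits = length(es),
        coverage_est = cov, weighted_delta = wsum,
        score = cov + wsum / wnorm,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, cands)
  out <- out[!duplicated(out$primer_sequence), , drop = FALSE]
  out <- out[order(-out$score, out$edits, out$primer_sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}
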