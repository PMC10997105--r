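# Shared fixture builders. All fixtures are constructed in code; nothing is
# read from disk except the packaged primer tables.

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A non-degenerate toy primer pair with wide length bounds.
toy_pair <- function(min_len = 20L, max_len = 400L) {
  primer_pair("toy", "ATGGCCTACGATTGCA", "AGGTCGAATCCTGTCA",
              min_len, max_len)
}

# Template carrying exactly one planted site pair for `pair`:
# left flank + forward primer + region + revcomp(reverse primer) + right
# flank. Degenerate primer positions are realized to their first base.
realize <- function(primer) {
  paste(vapply(strsplit(primer, "")[[1]],
               function(ch) iupac_bases(ch)[1], character(1)),
        collapse = "")
}

planted_template <- function(pair, region, flank = 15L) {
  paste0(random_seq(flank), realize(pair$forward), region,
         revcomp(realize(pair$reverse)), random_seq(flank))
}

# Reference data frame with one planted record per supplied lineage row.
make_records <- function(pair, lineages, region_len = 60L,
                         regions = NULL, flank = 15L) {
  n <- nrow(lineages)
  if (is.null(regions)) {
    regions <- vapply(seq_len(n), function(i) random_seq(region_len),
                      character(1))
  }
  df <- data.frame(
    record_id = sprintf("rec%03d", seq_len(n)),
    sequence = vapply(regions, function(r) planted_template(pair, r, flank),
                      character(1), USE.NAMES = FALSE),
    source_tag = "fixture",
    stringsAsFactors = FALSE
  )
  for (r in CANONICAL_RANKS) {
    df[[r]] <- if (r %in% names(lineages)) lineages[[r]] else NA_character_
  }
  df
}

# Pure-R position-by-position set-intersection mismatch oracle, independent
# of the bit-set implementation under test.
naive_mismatches <- function(primer, window) {
  a <- strsplit(primer, "")[[1]]
  b <- strsplit(window, "")[[1]]
  sum(mapply(function(x, y) {
    length(intersect(iupac_bases(x), iupac_bases(y))) == 0
  }, a, b))
}

# Canonical per-hit key set for engine/oracle comparisons.
hit_key <- function(h) {
  if (nrow(h) == 0L) return(character(0))
  sort(paste(h$strand, h$fwd_start, h$fwd_end, h$rev_start, h$rev_end,
             h$mm_fwd, h$mm_rev, h$metabarcode, sep = "|"))
}
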