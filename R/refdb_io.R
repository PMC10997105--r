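#' @importFrom utils read.delim write.table
#' @include taxonomy.R
NULL

# A reference database is an ordinary data frame with one row per sequence:
# columns record_id, sequence, source_tag, then one column per canonical rank
# (NA = unannotated). Sequences are stored uppercase with U mapped to T.

.RECORD_COLS <- c("record_id", "sequence", "source_tag", CANONICAL_RANKS)

.empty_records <- function() {
  df <- as.data.frame(setNames(rep(list(character(0)), length(.RECORD_COLS)),
                               .RECORD_COLS))
  df
}

.empty_exclusions <- function() {
  data.frame(record_id = character(0), reason = character(0),
             detail = character(0), stringsAsFactors = FALSE)
}

# Structural validation of one record row; returns NULL if valid, else
# c(reason, detail). Lineages must be annotated at family level or better and
# be prefix-complete downward from family (species implies genus implies
# family).
.validate_record <- function(seq, lin) {
  if (is.na(seq) || nchar(seq) == 0L) {
    return(c("empty_sequence", ""))
  }
  bad <- .invalid_iupac_positions(seq)
  if (length(bad) > 0L) {
    ch <- substr(seq, bad[1], bad[1])
    return(c("invalid_character",
             sprintf("invalid character '%s' at position %d", ch, bad[1])))
  }
  if (is.na(lin[["phylum"]])) return(c("missing_phylum", ""))
  if (is.na(lin[["family"]])) return(c("missing_family", ""))
  if (!is.na(lin[["species"]]) && is.na(lin[["genus"]])) {
    return(c("broken_lineage", "species annotated without genus"))
  }
  NULL
}

#' Read a lineage table
#'
#' Two dialects are accepted and auto-detected: a two-column key-value layout
#' `record_id<TAB>rank1=name1;rank2=name2;...`, and a seven-column fixed-rank
#' layout `record_id, phylum, class, order, family, genus, species` (with or
#' without a header row). Empty fields become `NA` (unannotated).
#'
#' @param source Path to a tab-separated lineage file.
#' @return Data frame with columns `record_id` and the canonical ranks.
#' @export
read_lineage_table <- function(source) {
  raw <- read.delim(source, header = FALSE, colClasses = "character",
                    stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (ncol(raw) == 2L) {
    out <- data.frame(record_id = raw[[1]], stringsAsFactors = FALSE)
    for (r in CANONICAL_RANKS) out[[r]] <- NA_character_
    for (i in seq_len(nrow(raw))) {
      if (is.na(raw[i, 2])) next
      pairs <- strsplit(strsplit(raw[i, 2], ";", fixed = TRUE)[[1]],
                        "=", fixed = TRUE)
      for (p in pairs) {
        key <- tolower(trimws(p[1]))
        if (key %in% CANONICAL_RANKS && length(p) == 2L) {
          out[i, key] <- trimws(p[2])
        }
      }
    }
    return(out)
  }
  if (ncol(raw) == 7L) {
    if (tolower(raw[1, 1]) == "record_id") raw <- raw[-1, , drop = FALSE]
    names(raw) <- c("record_id", CANONICAL_RANKS)
    rownames(raw) <- NULL
    return(raw)
  }
  stop("lineage table must have 2 (key-value) or 7 (fixed-rank) columns, got ",
       ncol(raw))
}

#' Read a reference database (FASTA + lineage table)
#'
#' Every FASTA entry with a structurally valid sequence and a lineage row
#' becomes one record; entries failing validation, entries without a lineage,
#' and lineage rows without a FASTA entry are reported in `rejected` with
#' machine-readable reasons — never silently dropped.
#'
#' @param fasta_source Path to a FASTA file of reference sequences. The
#'   record id is the first whitespace-delimited token of each header.
#' @param lineage_source Path to a lineage table (see [read_lineage_table()]).
#' @return List with elements `records` (reference data frame) and `rejected`
#'   (data frame `record_id, reason, detail`).
#' @export
read_reference_db <- function(fasta_source, lineage_source) {
  seqs <- tryCatch(
    Biostrings::readBStringSet(fasta_source),
    error = function(e) {
      stop("malformed FASTA in '", fasta_source, "': ", conditionMessage(e))
    }
  )
  headers <- names(seqs)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1)
  if (anyDuplicated(ids)) {
    stop("duplicate record_id in FASTA: '", ids[duplicated(ids)][1], "'")
  }
  lin <- read_lineage_table(lineage_source)
  if (anyDuplicated(lin$record_id)) {
    stop("duplicate record_id in lineage table: '",
         lin$record_id[duplicated(lin$record_id)][1], "'")
  }
  rownames(lin) <- lin$record_id

  seq_chr <- chartr("U", "T", toupper(as.character(seqs)))

  status <- lapply(seq_along(ids), function(i) {
    id <- ids[i]
    if (!id %in% lin$record_id) return(c("missing_lineage", ""))
    fail <- .validate_record(seq_chr[i], unlist(lin[id, CANONICAL_RANKS]))
    if (!is.null(fail)) fail else NULL
  })
  ok <- vapply(status, is.null, logical(1))

  records <- data.frame(record_id = ids[ok], sequence = seq_chr[ok],
                        source_tag = headers[ok], stringsAsFactors = FALSE)
  lin_ok <- lin[ids[ok], CANONICAL_RANKS, drop = FALSE]
  rownames(lin_ok) <- NULL
  records <- cbind(records, lin_ok)
  if (nrow(records) == 0L) records <- .empty_records()

  orphans <- setdiff(lin$record_id, ids)
  rejected <- data.frame(
    record_id = c(ids[!ok], orphans),
    reason = c(vapply(status[!ok], `[`, character(1), 1),
               rep("no_sequence", length(orphans))),
    detail = c(vapply(status[!ok], `[`, character(1), 2),
               rep("", length(orphans))),
    stringsAsFactors = FALSE
  )
  list(records = records, rejected = rejected)
}

#' Filter a reference database to structurally valid, on-target records
#'
#' Excluded records are those failing structural validation (invalid
#' characters, missing or broken lineage) plus those whose phylum differs
#' from `target_phylum`. Kept and excluded always partition the input.
#'
#' @param records Reference data frame.
#' @param target_phylum Phylum name records must carry to be kept, or `NULL`
#'   to skip the phylum screen.
#' @return List with `kept` (data frame) and `excluded`
#'   (`record_id, reason, detail`).
#' @export
filter_records <- function(records, target_phylum = NULL) {
  if (nrow(records) == 0L) stop("records must be non-empty")
  reasons <- character(nrow(records))
  details <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    lrow <- unlist(records[i, CANONICAL_RANKS])
    fail <- .validate_record(records$sequence[i], lrow)
    if (!is.null(fail)) {
      reasons[i] <- fail[1]
      details[i] <- fail[2]
    } else if (!is.null(target_phylum) &&
               records$phylum[i] != target_phylum) {
      reasons[i] <- "non_target_phylum"
      details[i] <- records$phylum[i]
    }
  }
  keep <- reasons == ""
  if (!any(keep)) warning("no records kept after filtering")
  list(
    kept = records[keep, , drop = FALSE],
    excluded = data.frame(record_id = records$record_id[!keep],
                          reason = reasons[!keep],
                          detail = details[!keep],
                          stringsAsFactors = FALSE)
  )
}

#' Construct a primer pair
#'
#' @param name Primer pair name.
#' @param forward,reverse Primer sequences, 5'→3', IUPAC alphabet, 10–30 nt.
#' @param min_len,max_len Amplicon length bounds in bp, excluding both primer
#'   footprints.
#' @return Object of class `primer_pair`.
#' @export
primer_pair <- function(name, forward, reverse, min_len, max_len) {
  forward <- chartr("U", "T", toupper(forward))
  reverse <- chartr("U", "T", toupper(reverse))
  for (side in c("forward", "reverse")) {
    p <- if (side == "forward") forward else reverse
    bad <- .invalid_iupac_positions(p)
    if (length(bad) > 0L) {
      stop("primer '", name, "' ", side, " sequence has non-IUPAC character '",
           substr(p, bad[1], bad[1]), "' at position ", bad[1])
    }
    if (nchar(p) < 10L || nchar(p) > 30L) {
      stop("primer '", name, "' ", side, " sequence length ", nchar(p),
           " outside 10-30 nt")
    }
  }
  min_len <- as.integer(min_len)
  max_len <- as.integer(max_len)
  if (is.na(min_len) || is.na(max_len) || min_len <= 0L ||
      min_len > max_len) {
    stop("primer '", name, "': need 0 < min_len <= max_len (got ",
         min_len, ", ", max_len, ")")
  }
  structure(list(name = name, forward = forward, reverse = reverse,
                 min_len = min_len, max_len = max_len),
            class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("<primer_pair> %s\n  F 5'-%s-3'\n  R 5'-%s-3'\n  amplicon %d-%d bp (excluding primers)\n",
              x$name, x$forward, x$reverse, x$min_len, x$max_len))
  invisible(x)
}

#' Read a primer table
#'
#' @param source Tab-separated file with columns
#'   `name, forward, reverse, min_len, max_len`.
#' @return Data frame of validated primer rows (degenerate IUPAC codes
#'   accepted). Use [as_primer_pairs()] to turn rows into `primer_pair`
#'   objects.
#' @export
read_primer_table <- function(source) {
  tab <- read.delim(source, header = TRUE, colClasses = "character",
                    stringsAsFactors = FALSE)
  need <- c("name", "forward", "reverse", "min_len", "max_len")
  if (!all(need %in% names(tab))) {
    stop("primer table must have columns: ", paste(need, collapse = ", "))
  }
  for (i in seq_len(nrow(tab))) {
    primer_pair(tab$name[i], tab$forward[i], tab$reverse[i],
                tab$min_len[i], tab$max_len[i])  # validation only
  }
  tab$min_len <- as.integer(tab$min_len)
  tab$max_len <- as.integer(tab$max_len)
  tab
}

#' Convert primer-table rows to primer_pair objects
#'
#' @param tab Data frame as returned by [read_primer_table()].
#' @return Named list of `primer_pair` objects.
#' @export
as_primer_pairs <- function(tab) {
  out <- lapply(seq_len(nrow(tab)), function(i) {
    primer_pair(tab$name[i], tab$forward[i], tab$reverse[i],
                tab$min_len[i], tab$max_len[i])
  })
  names(out) <- tab$name
  out
}

#' The packaged 18S metabarcoding primer set
#'
#' The 15 published primer pairs evaluated for nematode metabarcoding, with
#' their literature amplicon length bounds.
#'
#' @return Data frame as from [read_primer_table()].
#' @export
nematode_primer_set <- function() {
  read_primer_table(system.file("extdata", "primer_pairs_18S.tsv",
                                package = "primerscreen", mustWork = TRUE))
}

#' Write a reference database
#'
#' @param records Reference data frame.
#' @param fasta_path Output FASTA path.
#' @param lineage_path Output lineage TSV path (key-value dialect).
#' @export
write_reference_db <- function(records, fasta_path, lineage_path) {
  seqs <- Biostrings::BStringSet(setNames(records$sequence,
                                          records$record_id))
  Biostrings::writeXStringSet(seqs, fasta_path, width = 80L)
  keyval <- vapply(seq_len(nrow(records)), function(i) {
    lrow <- unlist(records[i, CANONICAL_RANKS])
    lrow <- lrow[!is.na(lrow)]
    paste(paste0(names(lrow), "=", lrow), collapse = ";")
  }, character(1))
  write.table(data.frame(records$record_id, keyval),
              lineage_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(c(fasta_path, lineage_path))
}

#' Write an exclusion report
#'
#' @param excluded Data frame `record_id, reason, detail` as produced by
#'   [filter_records()] or [read_reference_db()].
#' @param path Output TSV path.
#' @export
write_exclusion_report <- function(excluded, path) {
  write.table(excluded, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
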