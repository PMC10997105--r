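#' Canonical taxonomic ranks
#'
#' Rank order used throughout the package, from most to least inclusive.
#' Lineages are stored as one column per rank; `NA` marks an unannotated rank
#' (never an empty string).
#'
#' @export
CANONICAL_RANKS <- c("phylum", "class", "order", "family", "genus", "species")

#' Build a lineage
#'
#' @param phylum,class,order,family,genus,species Taxon names; `NA` where the
#'   record is not annotated at that rank.
#' @return Named character vector over the canonical ranks.
#' @export
lineage <- function(phylum = NA, class = NA, order = NA,
                    family = NA, genus = NA, species = NA) {
  out <- c(phylum = phylum, class = class, order = order,
           family = family, genus = genus, species = species)
  storage.mode(out) <- "character"
  out[!is.na(out) & out == ""] <- NA_character_
  out
}

.check_rank <- function(rank) {
  if (length(rank) != 1L || !rank %in% CANONICAL_RANKS) {
    stop("unknown rank '", rank, "'; canonical ranks are: ",
         paste(CANONICAL_RANKS, collapse = ", "))
  }
  rank
}

#' Taxon name at a rank
#'
#' @param lin Lineage (named character vector as from [lineage()]) or a
#'   one-row data frame with rank columns.
#' @param rank One of the canonical ranks.
#' @return Taxon name, or `NA_character_` if the lineage is unannotated at
#'   that rank.
#' @export
taxon_at <- function(lin, rank) {
  .check_rank(rank)
  if (is.data.frame(lin)) lin <- unlist(lin[1, CANONICAL_RANKS, drop = TRUE])
  val <- unname(lin[[rank]])
  if (is.null(val) || is.na(val) || val == "") NA_character_ else val
}

#' Do several lineages name the same taxon at a rank?
#'
#' @param lineages A data frame with rank columns (one row per lineage) or a
#'   list of lineage vectors.
#' @param rank One of the canonical ranks.
#' @return `"agree"` if every lineage is annotated at `rank` and all names are
#'   equal; `"incomplete"` if at least one lineage is unannotated at `rank`;
#'   `"disagree"` otherwise.
#' @export
same_taxon_at <- function(lineages, rank) {
  .check_rank(rank)
  if (is.data.frame(lineages)) {
    names_at <- as.character(lineages[[rank]])
  } else {
    names_at <- vapply(lineages, function(l) {
      v <- unname(l[[rank]])
      if (is.null(v)) NA_character_ else v
    }, character(1))
  }
  if (length(names_at) == 0L) stop("lineages must be non-empty")
  names_at[!is.na(names_at) & names_at == ""] <- NA_character_
  if (anyNA(names_at)) return("incomplete")
  if (length(unique(names_at)) == 1L) "agree" else "disagree"
}
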