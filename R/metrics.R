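# The three primer-performance statistics. Coverage is computed over all
# records; resolution is computed over unique metabarcodes (each unique
# metabarcode weighted once, using the designated hit per record);
# specificity is computed after one-sequence-per-species deduplication.

#' Taxonomic coverage
#'
#' Fraction of reference-database records amplified (at least one hit).
#'
#' @param result An `amplification_result` from [amplify_db()].
#' @return Fraction in `[0, 1]`.
#' @export
coverage <- function(result) {
  stopifnot(inherits(result, "amplification_result"))
  if (result$n_total == 0L) stop("empty database: coverage undefined")
  sum(result$amplified) / result$n_total
}

#' Group amplified records by unique metabarcode
#'
#' Uses the designated hit (shortest amplicon) per amplified record, so each
#' record contributes exactly one metabarcode. Groups partition the amplified
#' records: group sizes sum to the number of amplified records.
#'
#' @param result An `amplification_result`.
#' @param records The reference data frame the result came from.
#' @return Object of class `metabarcode_groups`: a list of groups, each with
#'   `metabarcode`, `record_ids` and `lineages` (data frame of rank columns).
#' @export
group_metabarcodes <- function(result, records) {
  stopifnot(inherits(result, "amplification_result"))
  des <- result$designated
  if (nrow(des) > 0L && !all(des$record_id %in% records$record_id)) {
    stop("hits reference records absent from the database")
  }
  rownames(records) <- records$record_id
  idx <- split(des$record_id, des$metabarcode)
  groups <- lapply(names(idx), function(mb) {
    ids <- idx[[mb]]
    list(metabarcode = mb, record_ids = ids,
         lineages = records[ids, CANONICAL_RANKS, drop = FALSE])
  })
  structure(groups, class = "metabarcode_groups")
}

#' @export
print.metabarcode_groups <- function(x, ...) {
  sizes <- vapply(x, function(g) length(g$record_ids), integer(1))
  cat(sprintf("<metabarcode_groups> %d unique metabarcodes over %d records\n",
              length(x), sum(sizes)))
  invisible(x)
}

#' Taxonomic resolution at a rank
#'
#' Fraction of unique metabarcodes whose producing taxa all carry the same
#' name at `rank`. A metabarcode shared by several species of one genus has
#' genus- and family-level but not species-level resolution. Groups with a
#' member unannotated at `rank` are by default excluded from both numerator
#' and denominator (so a primer is not penalized for annotation gaps);
#' `incomplete = "unresolved"` instead counts them in the denominator only.
#'
#' @param groups A `metabarcode_groups` object.
#' @param rank One of the canonical ranks.
#' @param incomplete How to treat groups with missing annotations at `rank`.
#' @return Fraction in `[0, 1]`, or `NA` (with a warning) when no group is
#'   assessable at `rank`.
#' @export
resolution <- function(groups, rank,
                       incomplete = c("exclude", "unresolved")) {
  stopifnot(inherits(groups, "metabarcode_groups"))
  incomplete <- match.arg(incomplete)
  if (length(groups) == 0L) {
    warning("no metabarcode groups: resolution undefined at rank ", rank)
    return(NA_real_)
  }
  verdicts <- vapply(groups, function(g) same_taxon_at(g$lineages, rank),
                     character(1))
  num <- sum(verdicts == "agree")
  den <- if (incomplete == "exclude") {
    sum(verdicts != "incomplete")
  } else {
    length(verdicts)
  }
  if (den == 0L) {
    warning("all groups incomplete at rank ", rank, ": resolution undefined")
    return(NA_real_)
  }
  num / den
}

#' Keep one sequence per species
#'
#' Retains a single, seeded-random record per distinct species name, to avoid
#' biases from the overrepresentation of model species. Records unannotated
#' at species level are kept as singletons keyed by record id.
#'
#' @param records Reference data frame.
#' @param seed Integer seed; the same seed always yields the same selection.
#' @return Subset of `records`, in original row order.
#' @export
dedup_one_per_species <- function(records, seed = 101L) {
  if (nrow(records) == 0L) return(records)
  key <- ifelse(is.na(records$species),
                paste0("record:", records$record_id),
                paste0("species:", records$species))
  keep_idx <- local({
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    vapply(split(seq_len(nrow(records)), key), function(ix) {
      if (length(ix) == 1L) ix else sample(ix, 1L)
    }, integer(1))
  })
  records[sort(unname(keep_idx)), , drop = FALSE]
}

#' Primer specificity
#'
#' Fraction of amplified records (after one-per-species deduplication)
#' belonging to the target phylum, plus the number of distinct target species
#' amplified.
#'
#' @param amplified_records Reference data frame restricted to the amplified,
#'   deduplicated records.
#' @param target_phylum Target phylum name.
#' @return List with `fraction` (`NA` with a warning when nothing was
#'   amplified) and `n_target_species`.
#' @export
specificity <- function(amplified_records, target_phylum) {
  n <- nrow(amplified_records)
  if (n == 0L) {
    warning("no amplified records: specificity undefined")
    return(list(fraction = NA_real_, n_target_species = 0L))
  }
  is_target <- !is.na(amplified_records$phylum) &
    amplified_records$phylum == target_phylum
  sp <- amplified_records$species[is_target]
  list(fraction = sum(is_target) / n,
       n_target_species = length(unique(sp[!is.na(sp)])))
}

#' Per-primer evaluation report
#'
#' One summary row per primer pair: coverage, amplicon length summaries over
#' designated hits (lengths exclude both primer footprints) and taxonomic
#' resolution at species, genus and family rank.
#'
#' @param result An `amplification_result`.
#' @param records The reference data frame the result came from.
#' @param incomplete Passed to [resolution()].
#' @return One-row data frame with columns `primer, coverage, mean_len,
#'   min_len_obs, max_len_obs, resolution_species, resolution_genus,
#'   resolution_family, n_amplified, n_total`.
#' @export
build_report <- function(result, records,
                         incomplete = c("exclude", "unresolved")) {
  stopifnot(inherits(result, "amplification_result"))
  incomplete <- match.arg(incomplete)
  n_amp <- sum(result$amplified)
  lens <- result$designated$amplicon_len
  if (n_amp > 0L) {
    groups <- group_metabarcodes(result, records)
    res <- vapply(c("species", "genus", "family"),
                  function(r) resolution(groups, r, incomplete), numeric(1))
  } else {
    warning("no amplification: resolutions undefined for ", result$primer)
    res <- c(species = NA_real_, genus = NA_real_, family = NA_real_)
  }
  data.frame(
    primer = result$primer,
    coverage = coverage(result),
    mean_len = if (n_amp > 0L) mean(lens) else NA_real_,
    min_len_obs = if (n_amp > 0L) min(lens) else NA_integer_,
    max_len_obs = if (n_amp > 0L) max(lens) else NA_integer_,
    resolution_species = unname(res["species"]),
    resolution_genus = unname(res["genus"]),
    resolution_family = unname(res["family"]),
    n_amplified = n_amp,
    n_total = result$n_total,
    stringsAsFactors = FALSE
  )
}
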