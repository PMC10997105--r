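# Synthetic reference databases with known ground truth. Each record is
#   left flank + forward-primer site + variable region + reverse site + right
# flank, where the two binding sites are realizations of the primers carrying
# a controlled number of true mismatches (the substituted base always falls
# outside the primer's IUPAC set at that position, so sampled mismatch counts
# are exactly realized), and the variable region evolves down a
# family -> genus -> species taxonomy so inter-primer divergence controls
# resolution. Every generated instance is certified against the independent
# Biostrings-based oracle: each record must contain exactly the planted hit
# set (records where random sequence happens to create a spurious binding
# site are resampled), so the recorded bookkeeping is instance-exact for any
# seed, not merely in expectation.

#' Synthetic database configuration
#'
#' @param seed Integer seed; the same seed and configuration yield
#'   byte-identical databases.
#' @param n_families,genera_per_family,species_per_genus,seqs_per_species
#'   Taxonomy shape.
#' @param target_fraction Fraction of families assigned to the target phylum
#'   (used by [generate_mixed_phylum_db()]).
#' @param binding_mismatch_target,binding_mismatch_nontarget Probability maps
#'   over mismatch counts `c("0", "1", "2", "3", "4+")` for the two clades;
#'   each applies independently to the forward and reverse site.
#' @param variable_region_length Length range (min, max) in bp of the
#'   inter-primer region; must sit within the primer pair's length bounds.
#' @param species_divergence,genus_divergence Per-site substitution
#'   probabilities applied along the species and genus branches.
#' @param shared_metabarcode_fraction Probability that a species (after the
#'   first of its genus) is forced to share its variable region with the
#'   previous species, creating metabarcodes without species-level
#'   resolution.
#' @param flank_length Length in bp of the random flanks outside the primer
#'   sites.
#' @param target_phylum Name used for the target clade.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed,
                             n_families = 8L,
                             genera_per_family = 3L,
                             species_per_genus = 3L,
                             seqs_per_species = 2L,
                             target_fraction = 0.5,
                             binding_mismatch_target =
                               c("0" = 0.65, "1" = 0.15, "2" = 0.05,
                                 "3" = 0.05, "4+" = 0.10),
                             binding_mismatch_nontarget =
                               c("0" = 0.20, "1" = 0.10, "2" = 0.10,
                                 "3" = 0.10, "4+" = 0.50),
                             variable_region_length = NULL,
                             species_divergence = 0.02,
                             genus_divergence = 0.08,
                             shared_metabarcode_fraction = 0.10,
                             flank_length = 12L,
                             target_phylum = "Nematoda") {
  chk_dist <- function(d, what) {
    if (!identical(sort(names(d)), sort(c("0", "1", "2", "3", "4+")))) {
      stop(what, " must be named over 0, 1, 2, 3, 4+")
    }
    if (any(d < 0) || abs(sum(d) - 1) > 1e-9) {
      stop(what, " probabilities must be non-negative and sum to 1")
    }
    d[c("0", "1", "2", "3", "4+")]
  }
  stopifnot(n_families >= 1L, genera_per_family >= 1L,
            species_per_genus >= 1L, seqs_per_species >= 1L,
            target_fraction >= 0, target_fraction <= 1,
            species_divergence >= 0, species_divergence < 1,
            genus_divergence >= 0, genus_divergence < 1,
            shared_metabarcode_fraction >= 0,
            shared_metabarcode_fraction <= 1,
            flank_length >= 0L)
  structure(list(
    seed = as.integer(seed),
    n_families = as.integer(n_families),
    genera_per_family = as.integer(genera_per_family),
    species_per_genus = as.integer(species_per_genus),
    seqs_per_species = as.integer(seqs_per_species),
    target_fraction = target_fraction,
    binding_mismatch_target = chk_dist(binding_mismatch_target,
                                       "binding_mismatch_target"),
    binding_mismatch_nontarget = chk_dist(binding_mismatch_nontarget,
                                          "binding_mismatch_nontarget"),
    variable_region_length = variable_region_length,
    species_divergence = species_divergence,
    genus_divergence = genus_divergence,
    shared_metabarcode_fraction = shared_metabarcode_fraction,
    flank_length = as.integer(flank_length),
    target_phylum = target_phylum
  ), class = "synthetic_config")
}

.rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.mutate_seq <- function(s, p) {
  if (p <= 0) return(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < p)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

# Realize a (possibly degenerate) primer as a concrete binding site carrying
# exactly k true mismatches: mismatch positions get a base outside the
# primer's IUPAC set there, all other positions a base inside it.
.realize_site <- function(primer, k) {
  chars <- strsplit(primer, "", fixed = TRUE)[[1]]
  sets <- lapply(chars, iupac_bases)
  site <- vapply(sets, function(b) b[sample.int(length(b), 1L)], character(1))
  mutable <- which(lengths(sets) < 4L)
  if (k > length(mutable)) {
    stop("cannot plant ", k, " true mismatches: primer has only ",
         length(mutable), " non-N positions")
  }
  if (k > 0L) {
    at <- mutable[sample.int(length(mutable), k)]
    for (i in at) {
      off <- setdiff(c("A", "C", "G", "T"), sets[[i]])
      site[i] <- off[sample.int(length(off), 1L)]
    }
  }
  paste(site, collapse = "")
}

.sample_mm <- function(dist) {
  cat_ <- sample(names(dist), 1L, prob = dist)
  if (cat_ == "4+") 4L else as.integer(cat_)
}

# Assemble one record around a species' variable region and certify it
# against the oracle. Returns the sequence or NULL when a spurious binding
# site survived all flank/site resampling attempts (caller then redraws the
# region).
.build_certified_record <- function(region, mm_f, mm_r, pair, flank_len,
                                    max_mismatches = 3L, tries = 8L) {
  amplifiable <- mm_f <= max_mismatches && mm_r <= max_mismatches
  for (t in seq_len(tries)) {
    fsite <- .realize_site(pair$forward, mm_f)
    rsite <- .realize_site(pair$reverse, mm_r)
    seqc <- paste0(.rand_seq(flank_len), fsite, region,
                   revcomp(rsite), .rand_seq(flank_len))
    hits <- oracle_amplify(seqc, pair, max_mismatches)
    ok <- if (amplifiable) {
      nrow(hits) == 1L && hits$strand == "+" &&
        hits$fwd_start == flank_len &&
        hits$metabarcode == region &&
        hits$mm_fwd == mm_f && hits$mm_rev == mm_r
    } else {
      nrow(hits) == 0L
    }
    if (ok) return(seqc)
  }
  NULL
}

# Shared generator core. `phylum_of` maps family index -> phylum name;
# `mm_dist_of` maps family index -> mismatch distribution; `per_species_mm`
# fixes the two mismatch counts once per species (all conspecific records
# share amplifiability) instead of once per sequence.
.generate_core <- function(config, pair, phylum_of, mm_dist_of,
                           per_species_mm) {
  vr <- config$variable_region_length
  if (is.null(vr)) {
    vr <- c(pair$min_len, min(pair$min_len + 40L, pair$max_len))
  }
  if (vr[1] > vr[2] || vr[1] < pair$min_len || vr[2] > pair$max_len) {
    stop("variable_region_length [", vr[1], ", ", vr[2],
         "] must sit within the primer pair's bounds [",
         pair$min_len, ", ", pair$max_len, "]")
  }

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)

  # --- taxonomy and species-level variable regions -------------------------
  species_tab <- list()
  for (f in seq_len(config$n_families)) {
    fam <- sprintf("Fam%03d", f)
    region_len <- if (vr[1] == vr[2]) vr[1] else {
      sample(seq(vr[1], vr[2]), 1L)
    }
    fam_region <- .rand_seq(region_len)
    for (g in seq_len(config$genera_per_family)) {
      gen <- sprintf("Gen%03d_%02d", f, g)
      gen_region <- .mutate_seq(fam_region, config$genus_divergence)
      prev_cluster <- NA_character_
      for (s in seq_len(config$species_per_genus)) {
        sp <- sprintf("Sp%03d_%02d_%02d", f, g, s)
        shared <- s > 1L &&
          stats::runif(1) < config$shared_metabarcode_fraction
        region <- if (shared) {
          species_tab[[length(species_tab)]]$region
        } else {
          .mutate_seq(gen_region, config$species_divergence)
        }
        cluster <- if (shared) prev_cluster else sp
        prev_cluster <- cluster
        species_tab[[length(species_tab) + 1L]] <- list(
          family = fam, genus = gen, species = sp,
          phylum = phylum_of(f), mm_dist = mm_dist_of(f),
          region = region, cluster = cluster, gen_region = gen_region,
          forced_shared = shared)
      }
    }
  }

  # --- per-species mismatch counts (mixed-phylum mode) ---------------------
  if (per_species_mm) {
    for (i in seq_along(species_tab)) {
      species_tab[[i]]$mm_f <- .sample_mm(species_tab[[i]]$mm_dist)
      species_tab[[i]]$mm_r <- .sample_mm(species_tab[[i]]$mm_dist)
    }
  }

  # --- records, with oracle certification ----------------------------------
  build_records <- function() {
    recs <- list()
    failed_clusters <- character(0)
    for (i in seq_along(species_tab)) {
      spx <- species_tab[[i]]
      for (r in seq_len(config$seqs_per_species)) {
        mm_f <- if (per_species_mm) spx$mm_f else .sample_mm(spx$mm_dist)
        mm_r <- if (per_species_mm) spx$mm_r else .sample_mm(spx$mm_dist)
        seqc <- .build_certified_record(spx$region, mm_f, mm_r, pair,
                                        config$flank_length)
        if (is.null(seqc)) {
          failed_clusters <- c(failed_clusters, spx$cluster)
          seqc <- NA_character_
        }
        recs[[length(recs) + 1L]] <- data.frame(
          record_id = sprintf("%s_seq%02d", spx$species, r),
          sequence = seqc, source_tag = "synthetic",
          phylum = spx$phylum, class = NA_character_,
          order = NA_character_, family = spx$family, genus = spx$genus,
          species = spx$species, mm_fwd = mm_f, mm_rev = mm_r,
          region = spx$region, stringsAsFactors = FALSE)
      }
    }
    list(recs = do.call(rbind, recs),
         failed = unique(failed_clusters))
  }

  built <- build_records()
  rounds <- 0L
  while (length(built$failed) > 0L && rounds < 5L) {
    rounds <- rounds + 1L
    # a spurious site lives in the shared variable region: redraw the region
    # for every species of the affected cluster, then rebuild everything so
    # the draw stream stays deterministic in (seed, config)
    for (cl in built$failed) {
      idx <- which(vapply(species_tab, function(x) x$cluster, "") == cl)
      new_region <- .mutate_seq(species_tab[[idx[1]]]$gen_region,
                                max(config$species_divergence, 0.01))
      for (i in idx) species_tab[[i]]$region <- new_region
    }
    built <- build_records()
  }
  if (length(built$failed) > 0L) {
    stop("could not certify a spurious-site-free instance for clusters: ",
         paste(built$failed, collapse = ", "),
         "; the configuration is infeasible for this primer pair")
  }
  recs <- built$recs

  records <- recs[, .RECORD_COLS]
  bookkeeping <- recs[, c("record_id", "phylum", "family", "genus",
                          "species", "mm_fwd", "mm_rev", "region")]
  bookkeeping$amplifiable <- bookkeeping$mm_fwd <= 3L &
    bookkeeping$mm_rev <= 3L
  list(records = records, bookkeeping = bookkeeping)
}

# Independent resolution bookkeeping over the generator's own records (no
# metrics-module code): group amplifiable records by region string and check
# taxon-name agreement per rank.
.gt_resolution <- function(bk) {
  amp <- bk[bk$amplifiable, , drop = FALSE]
  if (nrow(amp) == 0L) {
    return(c(species = NA_real_, genus = NA_real_, family = NA_real_))
  }
  out <- c(species = 0, genus = 0, family = 0)
  groups <- split(amp, amp$region)
  for (rank in names(out)) {
    agree <- vapply(groups, function(g) {
      length(unique(g[[rank]])) == 1L
    }, logical(1))
    out[rank] <- sum(agree) / length(groups)
  }
  out
}

#' Generate a synthetic reference database with certified ground truth
#'
#' @param config A [synthetic_config()].
#' @param pair The [primer_pair()] whose binding sites are planted.
#' @return List with `records` (reference data frame, all in the target
#'   phylum) and `ground_truth`: per-record bookkeeping (`mm_fwd`, `mm_rev`,
#'   `amplifiable`, planted `region` = expected metabarcode), plus instance
#'   summaries `coverage`, `resolution` (species/genus/family over unique
#'   metabarcodes of amplifiable records) and `n_unique_metabarcodes`.
#' @export
generate_db <- function(config, pair) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(pair, "primer_pair"))
  core <- .generate_core(
    config, pair,
    phylum_of = function(f) config$target_phylum,
    mm_dist_of = function(f) config$binding_mismatch_target,
    per_species_mm = FALSE)
  bk <- core$bookkeeping
  list(records = core$records,
       ground_truth = list(
         per_record = bk,
         coverage = mean(bk$amplifiable),
         resolution = .gt_resolution(bk),
         n_unique_metabarcodes =
           length(unique(bk$region[bk$amplifiable]))))
}

#' Generate a mixed-phylum database for specificity testing
#'
#' Target and non-target clades carry separate binding-site mismatch
#' distributions; species multiplicities above one exercise the
#' one-per-species deduplication. Binding-site mismatch counts are sampled
#' once per species (conspecific records share amplifiability), so the
#' expected post-deduplication specificity is exact on the instance
#' regardless of which conspecific record the seeded deduplication keeps.
#'
#' @inheritParams generate_db
#' @return As [generate_db()], with ground-truth elements
#'   `expected_specificity` (fraction of amplified post-dedup records in the
#'   target phylum) and `n_target_species_amplified`.
#' @export
generate_mixed_phylum_db <- function(config, pair) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(pair, "primer_pair"))
  if (config$target_fraction <= 0 || config$target_fraction >= 1) {
    stop("target_fraction must lie strictly between 0 and 1")
  }
  n_target <- min(config$n_families - 1L,
                  max(1L, round(config$target_fraction * config$n_families)))
  core <- .generate_core(
    config, pair,
    phylum_of = function(f) {
      if (f <= n_target) config$target_phylum
      else sprintf("NonTargetPhylum%02d", ((f - n_target - 1L) %% 3L) + 1L)
    },
    mm_dist_of = function(f) {
      if (f <= n_target) config$binding_mismatch_target
      else config$binding_mismatch_nontarget
    },
    per_species_mm = TRUE)
  bk <- core$bookkeeping
  sp <- bk[!duplicated(bk$species), , drop = FALSE]  # one row per species
  amp_sp <- sp[sp$amplifiable, , drop = FALSE]
  is_target <- amp_sp$phylum == config$target_phylum
  list(records = core$records,
       ground_truth = list(
         per_record = bk,
         coverage = mean(bk$amplifiable),
         expected_specificity = if (nrow(amp_sp) == 0L) NA_real_ else {
           sum(is_target) / nrow(amp_sp)
         },
         n_target_species_amplified = sum(is_target),
         n_species = nrow(sp)))
}

#' Write generator ground truth as JSON
#'
#' @param ground_truth The `ground_truth` element of [generate_db()] or
#'   [generate_mixed_phylum_db()].
#' @param path Output JSON path.
#' @export
write_ground_truth <- function(ground_truth, path) {
  if (!is.null(ground_truth$resolution)) {
    # keep rank names through JSON (named atomic vectors drop names)
    ground_truth$resolution <- as.list(ground_truth$resolution)
  }
  jsonlite::write_json(ground_truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
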