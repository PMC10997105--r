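test_that("coverage is the fraction of amplified records", {
  set.seed(21)
  pair <- toy_pair()
  lin <- data.frame(phylum = "Nematoda", family = "FamA",
                    genus = "GenA", species = sprintf("Sp%02d", 1:4))
  recs <- make_records(pair, lin)
  recs$sequence[4] <- random_seq(200)  # no binding sites
  res <- amplify_db(recs, pair, 3)
  expect_equal(coverage(res), 0.75)

  all_amp <- amplify_db(recs[1:3, ], pair, 3)
  expect_equal(coverage(all_amp), 1.0)
  expect_error(coverage(amplify_db(recs[0, ], pair, 3)), "empty")
})

test_that("metabarcode groups partition the amplified records", {
  set.seed(22)
  pair <- toy_pair()
  lin <- data.frame(phylum = "Nematoda", family = "FamA", genus = "GenA",
                    species = sprintf("Sp%02d", 1:5))
  recs <- make_records(pair, lin)  # five distinct regions
  res <- amplify_db(recs, pair, 3)
  groups <- group_metabarcodes(res, recs)
  expect_length(groups, 5L)
  sizes <- vapply(groups, function(g) length(g$record_ids), integer(1))
  expect_equal(sum(sizes), sum(res$amplified))
  expect_true(all(sizes == 1L))

  # two records share one metabarcode by construction
  shared <- random_seq(60)
  recs2 <- make_records(pair, lin[1:2, ],
                        regions = c(shared, shared))
  g2 <- group_metabarcodes(amplify_db(recs2, pair, 3), recs2)
  expect_length(g2, 1L)
  expect_setequal(g2[[1]]$record_ids, c("rec001", "rec002"))
})

test_that("resolution matches the shared-metabarcode semantics per rank", {
  set.seed(23)
  pair <- toy_pair()
  # two species of one genus sharing a metabarcode: genus- and family-level
  # but not species-level resolution
  shared <- random_seq(60)
  lin <- data.frame(phylum = "Nematoda", family = "Rhabditidae",
                    genus = "Caenorhabditis",
                    species = c("C. elegans", "C. briggsae"))
  recs <- make_records(pair, lin, regions = c(shared, shared))
  groups <- group_metabarcodes(amplify_db(recs, pair, 3), recs)
  expect_length(groups, 1L)
  expect_equal(resolution(groups, "species"), 0)
  expect_equal(resolution(groups, "genus"), 1)
  expect_equal(resolution(groups, "family"), 1)

  # all singleton groups with full lineages resolve at every rank
  lin2 <- data.frame(phylum = "Nematoda", family = c("F1", "F2"),
                     genus = c("G1", "G2"), species = c("S1", "S2"))
  recs2 <- make_records(pair, lin2)
  g2 <- group_metabarcodes(amplify_db(recs2, pair, 3), recs2)
  for (r in c("species", "genus", "family")) {
    expect_equal(resolution(g2, r), 1.0)
  }
})

test_that("groups with members unannotated at the rank are excluded or counted per flag", {
  set.seed(24)
  pair <- toy_pair()
  regions <- c(rep(random_seq(60), 2), random_seq(60))
  lin <- data.frame(phylum = "Nematoda", family = "FamA",
                    genus = c("GenA", "GenA", "GenB"),
                    species = c("SpA", NA, "SpC"))
  recs <- make_records(pair, lin, regions = regions)
  groups <- group_metabarcodes(amplify_db(recs, pair, 3), recs)
  expect_length(groups, 2L)
  # the shared group is incomplete at species rank: dropped from both sides
  expect_equal(resolution(groups, "species"), 1 / 1)
  # ... or kept in the denominator as unresolved
  expect_equal(resolution(groups, "species", incomplete = "unresolved"),
               1 / 2)
  expect_equal(resolution(groups, "genus"), 1.0)  # both groups agree there

  only_na <- group_metabarcodes(
    amplify_db(recs[2, , drop = FALSE], pair, 3),
    recs[2, , drop = FALSE])
  expect_warning(val <- resolution(only_na, "species"), "undefined")
  expect_true(is.na(val))
})

test_that("dedup keeps exactly one seeded-random record per species", {
  set.seed(25)
  pair <- toy_pair()
  lin <- data.frame(phylum = "Nematoda", family = "FamA", genus = "GenA",
                    species = rep("SpA", 10))
  recs <- make_records(pair, lin)
  expect_equal(nrow(dedup_one_per_species(recs, seed = 3)), 1L)

  # 100 records over 40 species with known multiplicities
  species <- sprintf("Sp%02d", rep(1:40, times = c(rep(4, 20), rep(1, 20))))
  lin2 <- data.frame(phylum = "Nematoda", family = "FamA", genus = "GenA",
                     species = species)
  recs2 <- make_records(pair, lin2, region_len = 30)
  d1 <- dedup_one_per_species(recs2, seed = 9)
  expect_equal(nrow(d1), 40L)
  expect_equal(d1, dedup_one_per_species(recs2, seed = 9))

  # records without species annotation survive as singletons
  lin3 <- data.frame(phylum = "Nematoda", family = "FamA",
                     genus = NA, species = NA)
  recs3 <- make_records(pair, rbind(lin3, lin3), region_len = 30)
  expect_equal(nrow(dedup_one_per_species(recs3, seed = 1)), 2L)
})

test_that("specificity is the target fraction of amplified records", {
  lin <- data.frame(
    phylum = c(rep("Nematoda", 5), rep("Arthropoda", 45)),
    family = "FamA", genus = "GenA",
    species = sprintf("Sp%02d", 1:50), stringsAsFactors = FALSE)
  recs <- make_records(toy_pair(), lin, region_len = 25)
  s <- specificity(recs, "Nematoda")
  expect_equal(s$fraction, 0.10)
  expect_equal(s$n_target_species, 5L)
  expect_equal(specificity(recs[1:5, ], "Nematoda")$fraction, 1.0)
  expect_warning(s0 <- specificity(recs[0, ], "Nematoda"), "undefined")
  expect_true(is.na(s0$fraction))
})

test_that("evaluation reports satisfy their structural invariants", {
  cfg <- synthetic_config(seed = 26, n_families = 4,
                          genera_per_family = 2, species_per_genus = 3,
                          seqs_per_species = 1)
  pair <- toy_pair(30, 400)
  db <- generate_db(cfg, pair)
  res <- amplify_db(db$records, pair, 3)
  rep <- build_report(res, db$records)
  expect_lte(rep$resolution_species, rep$resolution_genus)
  expect_lte(rep$resolution_genus, rep$resolution_family)
  expect_lte(rep$n_amplified, rep$n_total)
  expect_equal(rep$coverage, rep$n_amplified / rep$n_total)
  expect_gte(rep$min_len_obs, pair$min_len)
  expect_lte(rep$max_len_obs, pair$max_len)

  # zero amplification: coverage 0, resolutions undefined
  dead <- db$records
  dead$sequence <- vapply(seq_len(nrow(dead)),
                          function(i) random_seq(100), character(1))
  expect_warning(rep0 <- build_report(amplify_db(dead, pair, 0), dead),
                 "no amplification")
  expect_equal(rep0$coverage, 0)
  expect_true(is.na(rep0$resolution_species))
})
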