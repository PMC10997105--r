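test_that("the same seed and configuration yield byte-identical databases", {
  pair <- toy_pair()
  cfg <- synthetic_config(seed = 71, n_families = 3, genera_per_family = 2,
                          species_per_genus = 2, seqs_per_species = 2)
  a <- generate_db(cfg, pair)
  b <- generate_db(cfg, pair)
  expect_identical(a$records, b$records)
  expect_identical(a$ground_truth$per_record, b$ground_truth$per_record)

  fa1 <- tempfile(); fa2 <- tempfile(); l1 <- tempfile(); l2 <- tempfile()
  write_reference_db(a$records, fa1, l1)
  write_reference_db(b$records, fa2, l2)
  expect_identical(readLines(fa1), readLines(fa2))
  expect_identical(readLines(l1), readLines(l2))

  c <- generate_db(synthetic_config(seed = 72, n_families = 3,
                                    genera_per_family = 2,
                                    species_per_genus = 2,
                                    seqs_per_species = 2), pair)
  expect_false(identical(a$records$sequence, c$records$sequence))
})

test_that("an all-zero mismatch distribution gives full amplification", {
  pair <- toy_pair()
  cfg <- synthetic_config(seed = 73, n_families = 3, genera_per_family = 2,
                          species_per_genus = 2, seqs_per_species = 1,
                          binding_mismatch_target =
                            c("0" = 1, "1" = 0, "2" = 0, "3" = 0, "4+" = 0))
  db <- generate_db(cfg, pair)
  expect_equal(db$ground_truth$coverage, 1.0)
  expect_equal(coverage(amplify_db(db$records, pair, 3)), 1.0)
})

test_that("an all-4+ mismatch distribution gives zero amplification", {
  pair <- toy_pair()
  cfg <- synthetic_config(seed = 74, n_families = 3, genera_per_family = 2,
                          species_per_genus = 2, seqs_per_species = 1,
                          binding_mismatch_target =
                            c("0" = 0, "1" = 0, "2" = 0, "3" = 0, "4+" = 1))
  db <- generate_db(cfg, pair)
  expect_equal(db$ground_truth$coverage, 0)
  expect_equal(coverage(amplify_db(db$records, pair, 3)), 0)
})

test_that("ground-truth bookkeeping is certified by the independent oracle", {
  pair <- toy_pair()
  cfg <- synthetic_config(seed = 75, n_families = 3, genera_per_family = 2,
                          species_per_genus = 2, seqs_per_species = 1)
  db <- generate_db(cfg, pair)
  bk <- db$ground_truth$per_record
  for (i in seq_len(nrow(db$records))) {
    hits <- oracle_amplify(db$records$sequence[i], pair, 3)
    if (bk$amplifiable[i]) {
      expect_equal(nrow(hits), 1L)
      expect_equal(hits$metabarcode, bk$region[i])
      expect_equal(hits$mm_fwd, bk$mm_fwd[i])
      expect_equal(hits$mm_rev, bk$mm_rev[i])
    } else {
      expect_equal(nrow(hits), 0L)
    }
  }
})

test_that("forced metabarcode sharing produces species-unresolved groups", {
  pair <- toy_pair()
  cfg <- synthetic_config(seed = 76, n_families = 4, genera_per_family = 2,
                          species_per_genus = 3, seqs_per_species = 1,
                          shared_metabarcode_fraction = 0.6,
                          binding_mismatch_target =
                            c("0" = 1, "1" = 0, "2" = 0, "3" = 0, "4+" = 0))
  db <- generate_db(cfg, pair)
  bk <- db$ground_truth$per_record
  shared <- table(bk$region)
  expect_true(any(shared > 1))  # at least one shared metabarcode
  expect_lt(db$ground_truth$resolution["species"], 1)
  expect_equal(unname(db$ground_truth$resolution["family"]), 1)
})

test_that("a variable region outside the primer bounds is rejected", {
  pair <- toy_pair(50, 100)
  cfg <- synthetic_config(seed = 77, variable_region_length = c(150, 200))
  expect_error(generate_db(cfg, pair), "bounds")
  expect_error(synthetic_config(seed = 1, binding_mismatch_target =
                                  c("0" = 0.5, "1" = 0.5)),
               "named over")
})

test_that("mixed-phylum instances carry exact post-dedup specificity bookkeeping", {
  pair <- toy_pair()
  cfg <- synthetic_config(seed = 78, n_families = 6, genera_per_family = 2,
                          species_per_genus = 2, seqs_per_species = 2,
                          target_fraction = 0.5)
  mx <- generate_mixed_phylum_db(cfg, pair)
  expect_setequal(unique(mx$records$phylum[
    grepl("^Fam00[123]", mx$records$family)]), "Nematoda")

  ded <- dedup_one_per_species(mx$records, seed = 101)
  expect_equal(nrow(ded), mx$ground_truth$n_species)
  res <- amplify_db(ded, pair, 3)
  amp <- ded[ded$record_id %in% names(res$amplified)[res$amplified], ]
  s <- specificity(amp, "Nematoda")
  expect_equal(s$fraction, mx$ground_truth$expected_specificity)
  expect_equal(s$n_target_species,
               mx$ground_truth$n_target_species_amplified)

  # conspecific records share amplifiability, so any dedup seed agrees
  ded2 <- dedup_one_per_species(mx$records, seed = 999)
  res2 <- amplify_db(ded2, pair, 3)
  amp2 <- ded2[ded2$record_id %in% names(res2$amplified)[res2$amplified], ]
  expect_equal(specificity(amp2, "Nematoda")$fraction,
               mx$ground_truth$expected_specificity)
})

test_that("a non-target clade that never amplifies gives perfect specificity", {
  pair <- toy_pair()
  cfg <- synthetic_config(seed = 79, n_families = 4, genera_per_family = 2,
                          species_per_genus = 2, seqs_per_species = 1,
                          target_fraction = 0.5,
                          binding_mismatch_target =
                            c("0" = 1, "1" = 0, "2" = 0, "3" = 0, "4+" = 0),
                          binding_mismatch_nontarget =
                            c("0" = 0, "1" = 0, "2" = 0, "3" = 0, "4+" = 1))
  mx <- generate_mixed_phylum_db(cfg, pair)
  expect_equal(mx$ground_truth$expected_specificity, 1.0)
  ded <- dedup_one_per_species(mx$records, seed = 101)
  res <- amplify_db(ded, pair, 3)
  amp <- ded[ded$record_id %in% names(res$amplified)[res$amplified], ]
  expect_equal(specificity(amp, "Nematoda")$fraction, 1.0)
})

test_that("ground truth survives a JSON round trip", {
  pair <- toy_pair()
  cfg <- synthetic_config(seed = 80, n_families = 2, genera_per_family = 2,
                          species_per_genus = 2, seqs_per_species = 1)
  db <- generate_db(cfg, pair)
  path <- tempfile(fileext = ".json")
  write_ground_truth(db$ground_truth, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$coverage, db$ground_truth$coverage)
  expect_equal(nrow(back$per_record), nrow(db$ground_truth$per_record))
})
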