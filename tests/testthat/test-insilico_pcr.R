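test_that("iupac_mismatches counts empty-intersection positions", {
  expect_equal(iupac_mismatches("GTACACACCGCCCGTC", "GTACACACCGCCCGTC"), 0L)
  # S = {C,G}: compatible with C, incompatible with A
  expect_equal(iupac_mismatches("S", "C"), 0L)
  expect_equal(iupac_mismatches("S", "A"), 1L)
  expect_error(iupac_mismatches("ACGT", "ACG"), "lengths differ")
})

test_that("iupac_mismatches equals the set-intersection oracle on random pairs", {
  set.seed(77)
  alphabet <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                "B", "D", "H", "V", "N")
  for (i in 1:1000) {
    p <- paste(sample(alphabet, 18, replace = TRUE), collapse = "")
    w <- paste(sample(alphabet, 18, replace = TRUE), collapse = "")
    expect_equal(iupac_mismatches(p, w), naive_mismatches(p, w))
  }
})

test_that("find_binding_sites reports planted sites within the budget", {
  set.seed(5)
  primer <- "ATGGCCTACGATTGCA"
  seqc <- paste0(random_seq(100), primer, random_seq(80))
  sites <- find_binding_sites(seqc, primer, 0)
  expect_true(any(sites$start == 100 & sites$end == 116 &
                  sites$mismatches == 0))

  # four substitutions, all true mismatches, budget three: absent
  broken <- primer
  for (i in c(2, 6, 10, 14)) {
    base <- substr(broken, i, i)
    substr(broken, i, i) <- setdiff(c("A", "C", "G", "T"), base)[1]
  }
  seq2 <- paste0(random_seq(100), broken, random_seq(80))
  expect_false(any(find_binding_sites(seq2, primer, 3)$start == 100))
})

test_that("find_binding_sites equals the Biostrings all-windows oracle", {
  set.seed(6)
  primers <- c("ATGGCCTACGATTGCA", "TTTGTCTGSTTRATTSCG", "CACAGACCTGTTATTGC")
  for (i in 1:20) {
    seqc <- random_seq(sample(200:600, 1))
    for (p in primers) {
      got <- find_binding_sites(seqc, p, 3)
      want <- oracle_find_sites(seqc, p, 3)
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want)
    }
  }
})

test_that("amplify finds exactly the planted amplicon, bounds permitting", {
  set.seed(8)
  pair <- toy_pair(30, 400)
  region <- random_seq(200)
  tpl <- planted_template(pair, region)
  hits <- amplify(tpl, pair, 0)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$amplicon_len, 200L)
  expect_equal(hits$metabarcode, region)
  expect_equal(hits$mm_fwd + hits$mm_rev, 0L)

  narrow <- toy_pair(300, 700)
  expect_equal(nrow(amplify(tpl, narrow, 0)), 0L)
})

test_that("template ambiguity codes never add mismatches", {
  pair <- toy_pair()
  region <- random_seq(60)
  tpl <- planted_template(pair, region)
  # blur the first three bases of the forward footprint to N
  substr(tpl, 16, 18) <- "NNN"
  hits <- amplify(tpl, pair, 0)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$mm_fwd, 0L)
})

test_that("all hits satisfy the length, mismatch and coordinate invariants", {
  set.seed(9)
  pair <- toy_pair(20, 300)
  for (i in 1:25) {
    tpl <- paste0(random_seq(50), realize(pair$forward), random_seq(80),
                  realize(pair$forward), random_seq(60),
                  revcomp(realize(pair$reverse)), random_seq(50))
    hits <- amplify(tpl, pair, 3)
    if (nrow(hits) == 0) next
    expect_true(all(hits$amplicon_len >= pair$min_len &
                    hits$amplicon_len <= pair$max_len))
    expect_true(all(hits$mm_fwd <= 3 & hits$mm_rev <= 3))
    plus <- hits[hits$strand == "+", ]
    minus <- hits[hits$strand == "-", ]
    expect_true(all(plus$fwd_end <= plus$rev_start))
    expect_true(all(minus$rev_end <= minus$fwd_start))
    expect_true(all(nchar(hits$metabarcode) == hits$amplicon_len))
  }
})

test_that("raising the mismatch budget or widening bounds never removes hits", {
  set.seed(12)
  pair <- toy_pair(20, 200)
  for (i in 1:10) {
    tpl <- paste0(random_seq(40), realize(pair$forward), random_seq(90),
                  revcomp(realize(pair$reverse)), random_seq(40))
    prev <- character(0)
    for (mm in 0:3) {
      cur <- hit_key(amplify(tpl, pair, mm))
      expect_true(all(prev %in% cur))
      prev <- cur
    }
    narrow <- hit_key(amplify(tpl, toy_pair(80, 100), 3))
    wide <- hit_key(amplify(tpl, toy_pair(20, 400), 3))
    expect_true(all(narrow %in% wide))
  }
})

test_that("reverse-complementing the template preserves the metabarcode multiset", {
  set.seed(13)
  pair <- toy_pair()
  for (i in 1:10) {
    tpl <- planted_template(pair, random_seq(70))
    a <- amplify(tpl, pair, 3)
    b <- amplify(revcomp(tpl), pair, 3)
    expect_equal(sort(a$metabarcode), sort(b$metabarcode))
    expect_equal(sort(a$amplicon_len), sort(b$amplicon_len))
  }
})

test_that("the designated hit is the shortest amplicon with deterministic tie-breaks", {
  set.seed(14)
  pair <- toy_pair(20, 400)
  # two forward sites upstream of one reverse site: two nested amplicons
  tpl <- paste0(random_seq(20), realize(pair$forward), random_seq(50),
                realize(pair$forward), random_seq(60),
                revcomp(realize(pair$reverse)), random_seq(20))
  recs <- data.frame(record_id = "r1", sequence = tpl,
                     source_tag = "t", phylum = "P", class = NA,
                     order = NA, family = "F", genus = "G", species = "S",
                     stringsAsFactors = FALSE)
  res <- amplify_db(recs, pair, 3)
  expect_gte(nrow(res$hits), 2L)
  expect_equal(nrow(res$designated), 1L)
  expect_equal(res$designated$amplicon_len, min(res$hits$amplicon_len))
})

test_that("amplify_db on an empty database returns an empty result", {
  recs <- make_records(toy_pair(),
                       data.frame(phylum = "P", family = "F"))[0, ]
  res <- amplify_db(recs, toy_pair(), 3)
  expect_equal(res$n_total, 0L)
  expect_equal(nrow(res$hits), 0L)
})
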