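---
title: "Methods: in silico screening of metabarcoding primer pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in silico screening of metabarcoding primer pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The amplification model

`primerscreen` predicts whether a primer pair amplifies a reference sequence
by sequence comparison alone. A candidate amplicon is a pair of binding
sites: a window matching the forward primer and, downstream on the same
strand, a window matching the reverse complement of the reverse primer. A
primer position matches a template position when the IUPAC base sets of the
two letters intersect; a mismatch is an empty intersection. Matching is
ungapped — indels in the binding site are not modelled — and the comparison
is symmetric in ambiguity codes, so a template `N` can never create a
mismatch. Both strands are scanned (the minus strand by scanning the reverse
complement), all valid site pairs are enumerated, and a sequence counts as
amplified when at least one pair satisfies:

* at most `max_mismatches` mismatches on the forward primer **and** at most
  `max_mismatches` on the reverse primer (a per-primer budget, not a summed
  one — default 3, the convention of ecoPCR-style screens);
* an inter-primer distance within the pair's `[min_len, max_len]` bounds.

The **metabarcode** is the inter-primer region with both primer footprints
excluded; every reported length uses that convention. The model deliberately
contains no annealing thermodynamics, no PCR-efficiency or bias simulation,
and no special treatment of 3'-terminal mismatches: those belong to primer
*interpretation*, and the only place the 3' end is privileged is the
refinement scan's position weighting (below).

### Multiple hits and the designated amplicon

A sequence can host several valid site pairs. All are enumerated, but the
metrics use one **designated hit** per record: the shortest amplicon, ties
broken by smaller forward-site start, then plus strand before minus. The
shortest-fragment rule mimics the preferential amplification of short
fragments in mixed-template PCR and, more importantly, makes every metric
deterministic. How multi-hit sequences should feed a resolution metric is
not settled by convention; weighting each unique metabarcode once, built
from designated hits, is this package's documented choice.

## The three statistics

**Coverage** is the amplified fraction of the database. **Resolution at rank
r** is computed over *unique metabarcodes*: group the designated hits by
exact metabarcode string, ask for each group whether all producing lineages
carry one name at rank *r*, and report agreeing groups / assessable groups.
Because curated databases contain records annotated only to family level, a
group may be *incomplete* at a rank (some member unannotated there). The
default excludes incomplete groups from numerator and denominator at that
rank, so a primer is not penalized for annotation gaps; `incomplete =
"unresolved"` keeps them in the denominator for the pessimistic reading.
With lineages that are prefix-complete downward from family (enforced by the
reader), rank monotonicity holds on every input: species-level ≤ genus-level
≤ family-level resolution.

**Specificity** is measured on a mixed-taxon database after keeping one
sequence per species (seeded random choice, default seed 101, recorded in
run manifests): the target-phylum fraction of amplified records, plus the
count of distinct target species amplified. Without the deduplication,
heavily sequenced model species would dominate both numbers.

## Conservation matrices and the refinement scan

For logo building the package extracts, per designated hit, the template
region under a primer footprint, oriented as the primer reads it. Position
*i* of a window set gets nucleotide frequencies over A/C/G/T (template
ambiguity codes are dropped from that position's count — the alternative,
fractional allocation, changes nothing at the scale these logos are read)
and information content `2 − H_i`, with `H_i` the base-2 Shannon entropy and
`0·log 0 = 0`. The range is exactly 0 bits (uniform) to 2 bits (perfectly
conserved); no small-sample correction is applied by default, because the
statistic is defined by that range, but the classic `e(n)` subtraction is
available behind a flag for rendering parity with logo tools.

The refinement scan compares target and non-target partitions position by
position over the footprint extended by a 10-base flank on both sides
(windows that do not extend far enough are dropped). Its score is `delta =
non-target entropy − target entropy`: a good discriminator is conserved in
the target (low entropy) and variable outside it. Positions are weighted by
a linear ramp from 1.0 at the 5' end to 3.0 at the 3' end — "prefer 3'
discrimination" made reproducible; the endpoints are configurable and carry
no claim beyond monotonicity. `propose_variants()` enumerates shifts (up to
the flank) and re-specifications of up to `max_edits` positions to the
target consensus — the minimal IUPAC code covering bases with target
frequency ≥ 5%, a threshold that bounds degeneracy inflation — and scores
each candidate by estimated target coverage plus the normalized weighted
delta over its footprint. The normalizer is shift-independent, so at equal
coverage the ranking is strictly monotone in discriminating power; ties
break by fewer edits, then lexicographically. This scan is a defined,
reproducible procedure for the refinement idea; the original optimization it
echoes published no objective function or stopping rule, so no equivalence
is claimed.

## The resolution-length regression

Across primer pairs, species-level resolution is regressed on the log of
mean metabarcode length (natural log; R², F and p are base-invariant, so the
choice is cosmetic). With one predictor the package reports exact
`df = (1, n − 2)` and checks internally that `F = R²(n−2)/(1−R²)`.

The packaged published evaluation of the 15 18S pairs prints fractions to 2
decimals and lengths to 1. Refitting from those printed values gives
R² = 0.48, F(1,13) = 11.9, P = 0.004, whereas the original analysis — fitted
on unrounded resolutions — reported R² = 0.51, F(1,13) = 13.6, P = 0.003.
Perturbing the 2-decimal resolution column within its ±0.005 rounding band
moves the refitted R² across a range that comfortably contains 0.51, so the
discrepancy is a property of the printed table, not of the estimator; the
package keeps the printed values as-is rather than back-fitting hidden
digits.

## The synthetic generator and what a green test means

`generate_db()` builds records as *left flank + forward site + variable
region + reverse site + right flank*. Binding sites realize the primer
(degenerate positions drawn from their base sets) and then receive a sampled
number of **true** mismatches — each substituted base is chosen outside the
primer's IUPAC set at that position, so sampled mismatch counts are exactly
realized, never under-realized by a lucky substitution. The variable region
evolves by per-site substitution down a family → genus → species tree
(defaults 0.08 and 0.02 per site), all conspecific records share their
species region, and a configurable fraction of within-genus species pairs is
forced to share regions, planting metabarcodes with known species-level
ambiguity. Default shape — 8 families × 3 genera × 3 species × 2 sequences,
region length `[min_len, min_len + 40]`, 12 bp flanks — is a deliberately
small caricature of a curated reference database's family/genus/species
nesting; test configurations scale it down further (3–4 families, 12–64
records) to keep full runs fast.

Two design points deserve emphasis:

* **Certification.** Random flanks or regions can, rarely, contain a
  spurious binding site that would silently falsify the bookkeeping. Every
  record is therefore verified against an *independent* scan (built on
  `Biostrings::matchPattern`, sharing no code with the engine): amplifiable
  records must yield exactly the planted hit with the sampled mismatch
  counts, non-amplifiable ones no hit. Offending flanks are resampled and,
  if the spurious site sits in a shared region, the region cluster is
  redrawn. Ground truth is thus exact on the instance for *any* seed, and
  tests can demand equality, not approximation.
* **Per-species mismatch sampling in the mixed-phylum generator.** For the
  specificity test bed, binding-site mismatch counts are drawn once per
  species rather than per sequence, treating binding-site state as a species
  trait. Consequence: every conspecific record is equally amplifiable, and
  the expected post-deduplication specificity is exact regardless of which
  record the seeded deduplication keeps.

What passing tests show — and what they do not: the synthetic databases
exercise the engine's matching, strand handling, bounds, grouping and
bookkeeping against a known truth, but they do not mimic 18S secondary
structure, realistic branch lengths, indel variation in binding sites, or
the annotation noise of public databases. Exact parameter recovery on
synthetic data validates the *implementation*, not the biological
performance of any primer on real communities.

## Numerical and I/O conventions

* IUPAC letters are 4-bit sets; mismatch counting is a vectorized bitwise
  AND, and the oracle-equivalence tests pin it to both a pure set-intersection
  oracle and the Biostrings scan.
* Coordinates are 0-based half-open internally, 1-based inclusive in written
  amplicon tables. Sequences are uppercased and `U → T` on read.
* Records failing structural validation (non-IUPAC characters, missing or
  broken lineage, no lineage row) and off-target records are excluded with
  machine-readable reasons, never silently dropped; kept + excluded always
  partition the input.
* Run bundles (`report.tsv`, `specificity.tsv`, `regression.json`,
  `manifest.json`) carry parameters, seeds and input checksums. JSON numbers
  serialize at 15 significant digits, so comparisons across a JSON
  round-trip use a 1e-12 tolerance while in-memory comparisons are exact.

## Known limitations

Indel-tolerant matching, primer thermodynamics (Tm compatibility, dimers,
hairpins), abundance- or read-count-weighted metrics, and taxid-graph
operations (synonymy, LCA) are out of scope. Resolution estimates inherit
the completeness of the reference database: a genus represented by one
species trivially resolves at species level, so absolute resolution values
should be read against database density, and values from sparse databases
are optimistic.
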