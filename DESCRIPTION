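Package: primerscreen
Title: In Silico PCR Screening of Metabarcoding Primer Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Evaluates degenerate metabarcoding primer pairs against reference
    sequence databases by mismatch-tolerant in silico PCR. Implements an
    IUPAC-aware binding-site scan on both strands with per-primer mismatch
    budgets and amplicon length bounds, and derives the three standard primer
    performance statistics: taxonomic coverage (fraction of reference sequences
    amplified), taxonomic resolution at species, genus and family rank
    (fraction of unique metabarcodes whose producing taxa agree at that rank),
    and specificity against non-target taxa after one-sequence-per-species
    deduplication. Also provides per-position conservation (sequence-logo
    information content) matrices for primer-matching regions, a flank-aware
    variability scan for primer refinement, the resolution-versus-length
    regression, and a synthetic reference-database generator with certified
    ground truth for validating every metric.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Collate: 
    'conservation.R'
    'insilico_pcr.R'
    'iupac.R'
    'metrics.R'
    'primer_design.R'
    'taxonomy.R'
    'refdb_io.R'
    'reference_scan.R'
    'stats_report.R'
    'synthetic_data.R'
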