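#!/usr/bin/env Rscript
# Specificity of the Nema02 pair on the mixed-phylum database, conservation
# (sequence-logo) matrices for the target and non-target partitions, and the
# flank-aware variability scan with refined primer candidates.

suppressPackageStartupMessages(library(primerscreen))

dir <- "results/synthetic/mixed_phylum"
out <- "results/specificity"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

pair <- as_primer_pairs(nematode_primer_set())[["Nema02"]]
db <- read_reference_db(file.path(dir, "refdb.fasta"),
                        file.path(dir, "lineage.tsv"))
gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                          simplifyVector = TRUE)

# one sequence per species, then amplification and the target fraction
ded <- dedup_one_per_species(db$records, seed = 101)
res <- amplify_db(ded, pair, max_mismatches = 3)
amp <- ded[ded$record_id %in% names(res$amplified)[res$amplified], ]
spec <- specificity(amp, "Nematoda")
cat(sprintf("Specificity (Nematoda fraction of %d amplified, deduplicated records): %.3f\n",
            nrow(amp), spec$fraction))
cat(sprintf("  target species amplified: %d (expected from ground truth: %.3f, %d)\n",
            spec$n_target_species, gt$expected_specificity,
            gt$n_target_species_amplified))
write.table(data.frame(primer = pair$name, fraction = spec$fraction,
                       n_target_species = spec$n_target_species),
            file.path(out, "specificity.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# conservation matrices per partition and primer side
is_target <- db$records$phylum == "Nematoda"
for (part in c("target", "nontarget")) {
  recs <- db$records[if (part == "target") is_target else !is_target, ]
  for (side in c("forward", "reverse")) {
    w <- collect_primer_windows(res, recs, side, dedup = FALSE)
    if (length(w) == 0) next
    cm <- conservation_matrix(w)
    write_conservation_table(
      cm, file.path(out, sprintf("logo_%s_%s.tsv", part, side)))
    cat(sprintf("  %-9s %-7s logo: %3d windows, mean info %.2f bits\n",
                part, side, cm$n_sequences, mean(cm$info)))
  }
}

# variability scan over the forward footprint with 10-base flanks
tw <- collect_primer_windows(res, db$records[is_target, ], "forward",
                             flank = 10)
nw <- collect_primer_windows(res, db$records[!is_target, ], "forward",
                             flank = 10)
if (length(tw) > 0 && length(nw) > 0) {
  scan <- variability_scan(tw, nw, flank = 10)
  write_variability_scan(scan, file.path(out, "variability_scan.tsv"))
  top <- scan$table[order(scan$table$rank)[1:3], ]
  cat("Top discriminating positions (weighted delta, bits):\n")
  print(top[, c("position", "target_info", "nontarget_info",
                "weighted_delta")], row.names = FALSE)
  cand <- propose_variants(scan, pair$forward, max_shift = 2, max_edits = 1)
  write.table(cand, file.path(out, "candidates.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat(sprintf("Best refined forward-primer candidate: %s (shift %+d, %d edits, score %.3f)\n",
              cand$primer_sequence[1], cand$shift[1], cand$edits[1],
              cand$score[1]))
}
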