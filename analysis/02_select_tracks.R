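#!/usr/bin/env Rscript
# Select the tracks intersecting the seed structures (STN, SN, GP; SN and
# GP as composites of their parts) from the phantom tractogram, exactly as
# the full-scale analysis reduces its tractogram before any counting.
# Caches the per-track structure-visit sequences for the later stages.

suppressMessages(library(bgtract))

tract <- read_tck("scratch/phantom/phantom.tck")
volume <- read_label_volume("scratch/phantom/labels.nii.gz")
structures <- read_structure_set("scratch/phantom/structures.yaml")

sel <- select_seed_tracks(tract, volume, structures)

jsonlite::write_json(
  list(selected = sel$selected, n_total = sel$n_total,
       sequences = lapply(sel$sequences, unclass)),
  "scratch/selection.json", auto_unbox = FALSE, digits = NA)

truth <- jsonlite::read_json("scratch/phantom/ground_truth.json",
                             simplifyVector = TRUE)
summary <- data.frame(
  n_tracks_read = sel$n_total,
  n_selected = length(sel$selected),
  n_rejected = sel$n_total - length(sel$selected),
  expected_selected = truth$n_selected)
write.csv(summary, "results/02_selection_summary.csv", row.names = FALSE)

cat(sprintf("selected %d of %d tracks (expected %d); %d background tracks rejected\n",
            summary$n_selected, summary$n_tracks_read,
            summary$expected_selected, summary$n_rejected))
stopifnot(summary$n_selected == summary$expected_selected)
cat("selection matches the phantom's ground truth exactly\n")
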