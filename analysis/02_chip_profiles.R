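#!/usr/bin/env Rscript
# ChIP coverage stage: extend tags to 120 bp, sum per-bp coverage, divide by
# the genomic average, log2, standardize genome-wide (Z-scores), and average
# motif-centered profiles in 10-bp bins per class and condition. The
# scientific readout mirrors the factor-eviction experiment: enrichment at
# the motif drops between wild type and the ts mutant for both classes.

suppressPackageStartupMessages(library(memorychrom))

seed <- 42L
sim <- simulate_dataset(sim_config(seed = seed))
cls <- S4Vectors::mcols(sim$sites)$class_label

profiles <- list()
for (cond in names(sim$tags)) {
  z <- normalize_zscore(coverage_track(sim$tags[[cond]], sim$genome))
  for (cl in sort(unique(cls))) {
    p <- motif_centered_profile(z, sim$sites[cls == cl])
    p$condition <- cond
    p$class_label <- cl
    profiles[[paste(cond, cl)]] <- as.data.frame(p)
  }
}
long <- do.call(rbind, profiles)
dir.create("results", showWarnings = FALSE)
write_table_strict(long, "results/02_motif_profiles.tsv")

peaks <- do.call(rbind, lapply(profiles, function(p) {
  data.frame(condition = p$condition[1], class_label = p$class_label[1],
             peak_z = round(p$mean[p$offset == 0], 3))
}))
write_table_strict(peaks, "results/02_peak_summary.tsv")

message("Motif-centered Z-score profiles written; peak values at offset 0:")
message(paste(capture.output(print(peaks, row.names = FALSE)),
              collapse = "\n"))
message("Both classes lose motif enrichment in the ts condition (planted ",
        "5-fold -> 2-fold), matching the designed eviction contrast.")
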