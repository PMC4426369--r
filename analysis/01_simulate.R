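#!/usr/bin/env Rscript
# Build the default synthetic study: a 2 x 250-kb genome carrying 60 memory
# and 60 responsive promoters with identical planted motifs, upstream
# T-tract densities of 0.08 vs 0.02 per bp over [-200, -20), two ChIP tag
# libraries (wild type 5-fold, ts mutant 2-fold motif enrichment), and
# class-shifted expression/noise tables. Large per-bp artifacts go to
# scratch/; a compact summary lands in results/.

suppressPackageStartupMessages(library(memorychrom))

seed <- 42L
cfg <- sim_config(seed = seed)
sim <- simulate_dataset(cfg)
paths <- write_sim_output(sim, "scratch/sim")

cls <- S4Vectors::mcols(sim$sites)$class_label
summary <- data.frame(
  quantity = c("genome_bp", "n_chromosomes", "n_sites_memory",
               "n_sites_responsive", "n_tags_wt", "n_tags_ts",
               "mean_log2fc_memory", "mean_log2fc_responsive",
               "mean_noise_memory", "mean_noise_responsive"),
  value = c(sum(Biostrings::width(sim$genome)), length(sim$genome),
            sum(cls == "memory"), sum(cls == "responsive"),
            length(sim$tags$wt), length(sim$tags$ts),
            round(mean(sim$expression$log2fc[cls == "memory"]), 4),
            round(mean(sim$expression$log2fc[cls == "responsive"]), 4),
            round(mean(sim$metrics$noise[cls == "memory"]), 4),
            round(mean(sim$metrics$noise[cls == "responsive"]), 4)))
dir.create("results", showWarnings = FALSE)
write_table_strict(summary, "results/01_simulation_summary.tsv")

message("Simulated study written to scratch/sim (", length(paths),
        " files); summary:")
message(paste(capture.output(print(summary, row.names = FALSE)),
              collapse = "\n"))
message("Expression changes sit near -1 (responsive) vs 0 (memory) log2 ",
        "units and noise near -0.5 vs 0, the contrasts the later stages ",
        "must recover.")
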