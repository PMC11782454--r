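#!/usr/bin/env Rscript
# Runs the full fitness pipeline on the simulated screen written by
# 02_simulate_screen.R: size-factor normalization, per-replicate log2 fold
# changes vs generation 0, per-guide AUC fitness, correlation-weighted gene
# fitness with bootstrap CIs, control-based and between-condition Wilcoxon
# tests with BH correction, and the impact / combined scores. Also exports a
# bedGraph fitness track for the stress condition.

library(co2screen)
if (!file.exists("scratch/sim/counts.tsv"))
  stop("run analysis/02_simulate_screen.R first")
dir.create("results", showWarnings = FALSE)

res <- run_screen_analysis("scratch/sim/counts.tsv",
                           "scratch/sim/samples.csv",
                           "scratch/sim/library.tsv",
                           condition_a = "4pct", condition_b = "30pct",
                           bootstrap_reps = 1000, seed = 2,
                           out_dir = "results")

cat("Size factors (first 6):\n")
print(round(res$size_factors[1:6], 3))
cmp <- res$compare
cat(sprintf("\n%d genes scored; hit classes under stress (30pct):\n",
            nrow(cmp)))
print(table(cmp$class_b))
cat("\nTop genes by |combined score|:\n")
print(head(cmp[order(-abs(cmp$combined)), ], 8), digits = 3)

# browser-style fitness track: stress-condition guide fitness over the genome
lib <- read_library_annotation("scratch/sim/library.tsv")
gb <- res$guide_fitness[res$guide_fitness$condition == "30pct", ]
guides <- merge(lib, gb[, c("guide_id", "fitness")], by = "guide_id")
iv <- export_coverage_track(guides, "results/fitness_30pct.bedGraph",
                            track_name = "fitness_30pct")
cat(sprintf("\nWrote %d bedGraph intervals to results/fitness_30pct.bedGraph\n",
            nrow(iv)))
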