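#!/usr/bin/env Rscript
# Generates the benchmark synthetic screen: 2,000 genes x 5 guides + 500
# control guides under turbidostat selection in two conditions (benign
# "4pct", 4 replicates; stress "30pct", 3 replicates), sampled at
# generations 0/4/8/10 with 2e6 reads per sample. Writes the count table,
# sample sheet, library annotation and ground truth for the downstream
# fitting scripts (scratch/sim/; these are inputs regenerated on demand, not
# results).

library(co2screen)
dir.create("scratch/sim", recursive = TRUE, showWarnings = FALSE)

seed <- 1
sc <- default_recovery_scenario(seed = seed)
sim <- simulate_screen(sc$config)

write_count_table(sim$counts, "scratch/sim/counts.tsv")
write_sample_sheet(sim$samples, "scratch/sim/samples.csv")
write_library_annotation(sim$library, "scratch/sim/library.tsv")
write.table(sim$truth$gene, "scratch/sim/truth_genes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sim$truth$guide, "scratch/sim/truth_guides.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("Simulated %d guides x %d samples (seed %d)\n",
            nrow(sim$counts), ncol(sim$counts), seed))
cat(sprintf("  shifted genes (|delta s| = 0.3 between conditions): %d\n",
            sum(sim$truth$gene$shifted)))
cat(sprintf("  per-sample depth: %g reads\n", sum(sim$counts[, 1])))
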