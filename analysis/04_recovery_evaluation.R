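#!/usr/bin/env Rscript
# Evaluates the pipeline output of 03_fitness_pipeline.R against the
# simulator's ground truth: correlation of estimated gene fitness with the
# true selection coefficients, detection of genes whose selection shifts
# between conditions, control-guide neutrality, and a fitness-vs-fitness
# scatter in the style of a two-condition screen comparison.

library(co2screen)
for (f in c("results/compare.tsv", "scratch/sim/truth_genes.tsv"))
  if (!file.exists(f)) stop("run analysis/02 and 03 first (missing ", f, ")")

cmp <- read.delim("results/compare.tsv")
fa <- read.delim("results/fitness_A.tsv")
fb <- read.delim("results/fitness_B.tsv")
truth <- read.delim("scratch/sim/truth_genes.tsv", check.names = FALSE)

r_a <- cor(truth$`4pct`[match(fa$target_id, truth$target_id)], fa$fitness)
r_b <- cor(truth$`30pct`[match(fb$target_id, truth$target_id)], fb$fitness)
shifted <- truth$shifted[match(cmp$target_id, truth$target_id)]
called <- !is.na(cmp$p_adj) & cmp$p_adj < 0.05
metrics <- data.frame(
  metric = c("pearson_r_4pct", "pearson_r_30pct",
             "shifted_sensitivity_bh05", "observed_fdr_bh05",
             "n_called", "n_shifted"),
  value = c(r_a, r_b, mean(called[shifted]),
            sum(called & !shifted) / max(1, sum(called)),
            sum(called), sum(shifted)))
write.table(format(metrics, digits = 4), "results/recovery_metrics.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("Recovery metrics:\n")
print(metrics, digits = 4)

pdf("results/fitness_scatter.pdf", width = 5, height = 5)
plot(cmp$fitness_a, cmp$fitness_b, pch = 16, cex = 0.4,
     col = ifelse(shifted, "firebrick", "grey40"),
     xlab = "gene fitness, benign condition (4% CO2 analog)",
     ylab = "gene fitness, stress condition (30% CO2 analog)",
     main = "Simulated screen: fitness by condition")
abline(0, 1, lty = 2)
abline(2.5, 1, lty = 3); abline(-2.5, 1, lty = 3)
legend("topleft", c("shifted gene", "unshifted"), pch = 16,
       col = c("firebrick", "grey40"), bty = "n", cex = 0.8)
dev.off()
cat("Wrote results/fitness_scatter.pdf\n")
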