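#!/usr/bin/env Rscript
# Global insularity models: do oceanic-island endemics carry relatively
# larger brains once allometry and shared ancestry are controlled?

suppressPackageStartupMessages(library(islandbrains))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L

tree <- read_trees("results/data/tree.nwk")[[1]]
tab <- read_trait_table("results/data/traits.csv")
dir.create("results", showWarnings = FALSE)

cfg <- scaled_config(seed = seed + 1L, check_autocorr = FALSE)
fits <- suppressMessages(fit_global_models(tab, tree, cfg))

out <- do.call(rbind, lapply(names(fits), function(m) {
  s <- fits[[m]]$summary
  s$model <- m
  s$n <- fits[[m]]$n
  s
}))
write.table(out, "results/global_models.tsv", sep = "\t", row.names = FALSE)

b <- subset(out, model == "model1" & parameter == "insularity")
cat(sprintf(
  "Model 1 (N = %d): insularity beta mode = %.3f, HPD [%.3f, %.3f], pMCMC = %.3f\n",
  b$n, b$mode, b$ci_low, b$ci_high, b$pMCMC))
cat("The generator's island brain effect is 0.06; a positive beta of that",
    "order, with an interval excluding zero, reproduces the island-brain",
    "association.\nWrote results/global_models.tsv\n")
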