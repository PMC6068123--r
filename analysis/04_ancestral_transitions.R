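#!/usr/bin/env Rscript
# Two-step ancestral transition analysis: reconstruct the island history,
# classify nodes at the 90% posterior threshold, and contrast ancestral
# relative brain size across transition categories to separate in-situ
# evolution (gamma - beta) from colonization sorting (beta - alpha).

suppressPackageStartupMessages(library(islandbrains))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L

tree <- read_trees("results/data/tree.nwk")[[1]]
tab <- read_trait_table("results/data/traits.csv")
flags <- setNames(tab$insularity, tab$species)

rbs <- suppressWarnings(relative_brain_size(tab, tree))
cfg <- scaled_config(seed = seed + 4L, check_autocorr = FALSE)
res <- suppressWarnings(suppressMessages(
  ancestral_transition_analysis(tree, flags, rbs, cfg)))

cl <- attr(res$categories, "classification")
node_tab <- merge(cl, data.frame(node = names(res$node_values),
                                 brain_value = res$node_values))
write.table(node_tab, "results/ancestral_nodes.tsv", sep = "\t",
            row.names = FALSE)
write.table(res$categories, "results/transition_categories.tsv", sep = "\t",
            row.names = FALSE)
write.table(res$model$contrasts, "results/transition_contrasts.tsv",
            sep = "\t", row.names = FALSE)
write_annotated_tree(tree, cl, "results/annotated_tree.nwk")

counts <- table(res$categories$category)
cat("Classified ancestor-child links:",
    paste(names(counts), counts, sep = "=", collapse = ", "), "\n")
for (i in seq_len(nrow(res$model$contrasts))) {
  r <- res$model$contrasts[i, ]
  cat(sprintf("%s: mode = %.3f [%.3f, %.3f], pMCMC = %.3f\n",
              r$contrast, r$mode, r$ci_low, r$ci_high, r$pMCMC))
}
cat("Under the in-situ generator, gamma - beta should exceed beta - alpha.\n")
cat("Wrote results/{ancestral_nodes,transition_categories,transition_contrasts}.tsv\n")
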