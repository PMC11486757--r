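#!/usr/bin/env Rscript
# Differential-expression screen: BH-adjust the per-gene p-values, call DEGs
# at adjusted p < 0.05 with at least doubled (log2FC >= 1) or halved
# (log2FC <= -1) expression, and tally calls per arCOG functional class.

suppressPackageStartupMessages(library(chemoflux))

genes <- read_gene_stats("results/gene_stats.csv")
cls <- classify_degs(genes)   # computes padj from pvalue via BH
counts <- deg_counts(cls)
cat(sprintf("DEGs: %d up, %d down, %d unchanged (of %d genes)\n",
            counts[["up"]], counts[["down"]], counts[["none"]], nrow(cls)))

if ("is_true" %in% names(genes)) {
  tp <- sum(cls$class != "none" & genes$is_true)
  fp <- sum(cls$class != "none" & !genes$is_true)
  cat(sprintf("planted truth: %d/%d recovered, %d false discoveries (FDR target 0.05)\n",
              tp, sum(genes$is_true), fp))
}

utils::write.csv(cls, "results/deg_calls.csv", row.names = FALSE)
tal <- tally_arcog(cls)
utils::write.csv(tal, "results/arcog_tallies.csv", row.names = FALSE)
cat("arCOG classes with DEGs:", paste(tal$arcog, collapse = ", "), "\n")
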