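#!/usr/bin/env Rscript
# Generate every input the downstream analyses need: noisy chemostat
# measurement series for the three nutrient-availability conditions (five
# replicates each), the toy metabolic networks in the native JSON dialect,
# and a planted-truth per-gene statistics table.

suppressPackageStartupMessages(library(chemoflux))
dir.create("results", showWarnings = FALSE)

seed0 <- 20260920L
set.seed(seed0)

all_samples <- list()
for (cond in c("low", "high", "overfeed")) {
  sc <- chemostat_preset(cond)
  for (r in 1:5) {
    sim <- simulate_chemostat(sc, seed = seed0 + match(cond, c("low", "high", "overfeed")) * 100L + r,
                              replicate = r)
    all_samples[[length(all_samples) + 1L]] <- sim$samples
  }
  truth <- simulate_chemostat(sc, noise = FALSE)$truth
  cat(sprintf("%-9s mu_true %.3f 1/h, q_MSG %.4f, q_Glc %.4f g/g/h, C-balance_true %.2f\n",
              cond, truth$mu, truth$q_uptake[["msg"]], truth$q_uptake[["glucose"]],
              truth$c_balance_true))
}
samples <- do.call(rbind, all_samples)
utils::write.csv(samples, "results/chemostat_samples.csv", row.names = FALSE)
cat(sprintf("wrote %d sample rows (3 conditions x 5 replicates) to results/chemostat_samples.csv\n",
            nrow(samples)))

for (topo in c("chain", "dual_substrate", "branched_tca")) {
  tm <- make_toy_model(topo)
  write_native(tm$model, file.path("results", paste0("toy_", topo, ".json")))
  cat(sprintf("toy '%s': %d reactions, known optimum %.4f\n",
              topo, length(tm$model$reactions), tm$known_solution$objective_value))
}

genes <- simulate_de_table(n_genes = 2000, n_true = 50, effect = 2, seed = seed0)
utils::write.csv(genes, "results/gene_stats.csv", row.names = FALSE)
cat(sprintf("wrote %d-gene table with %d planted DEGs to results/gene_stats.csv\n",
            nrow(genes), sum(genes$is_true)))
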