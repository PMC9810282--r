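#!/usr/bin/env Rscript
# Group-average the raw cohort matrices, normalize, threshold at 10% graph
# density, binarize, and export the binary difference network for BrainNet
# Viewer. Reads results/cohort/ (run 01_simulate.R first).

suppressPackageStartupMessages(library(percnet))

atlas <- read_atlas(file.path("results", "cohort", "atlas.tsv"))
read_group <- function(group) {
  files <- list.files(file.path("results", "cohort"),
                      pattern = paste0("^", group, "_.*\\.csv$"),
                      full.names = TRUE)
  lapply(files, read_matrix, group = group)
}

for (group in c("control", "disease")) {
  ms <- read_group(group)
  avg <- threshold_proportional(normalize_matrix(group_average(ms)), 0.10)
  write_matrix(avg, file.path("results", paste0("avg_", group, ".csv")))
  cat(sprintf("%s: %d subjects -> %d edges at density %.4f, largest cluster %d/90\n",
              group, length(ms), n_edges(avg), graph_density(avg),
              largest_cluster_size(avg)))
  assign(paste0("avg_", group), avg)
}

diff <- binary_subtract(binarize(avg_control), binarize(avg_disease))
cat(sprintf("edge overlap: %d control-only, %d disease-only, %d shared\n",
            diff$counts["only_a"], diff$counts["only_b"], diff$counts["shared"]))
dm <- connectivity_matrix(abs(diff$difference), labels = avg_control$labels,
                          state = "binarized")
write_brainnet_files(dm, atlas, file.path("results", "brainnet_difference"))
cat("wrote results/avg_*.csv and results/brainnet_difference.{node,edge}\n")
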