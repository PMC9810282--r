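#!/usr/bin/env Rscript
# Full weighted quantifier battery on the thresholded group-average networks
# plus per-subject global quantifiers from individually prethresholded
# matrices. Reads results/ from 01-02.

suppressPackageStartupMessages(library(percnet))

seed <- 42L
for (group in c("control", "disease")) {
  avg <- read_matrix(file.path("results", paste0("avg_", group, ".csv")))
  avg$state <- "thresholded"  # written post-threshold
  gq <- global_quantifiers(avg, which = "all", seed = seed)
  write.csv(data.frame(metric = names(gq), value = unlist(gq)),
            file.path("results", paste0("global_", group, ".csv")),
            row.names = FALSE)
  nodal <- nodal_metrics(avg)
  nodal$ci <- collective_influence_scores(avg, ell = 2)
  comm <- community_metrics(avg, seed = seed)
  nodal$participation <- comm$participation
  nodal$module <- comm$partition
  write.csv(nodal, file.path("results", paste0("nodal_", group, ".csv")),
            row.names = FALSE)
  cat(sprintf("%s average: cpl %.2f, efficiency %.3f, Q %.3f, sigma %.2f, largest cluster %d\n",
              group, gq$cpl, gq$global_efficiency, gq$modularity,
              gq$small_worldness, gq$largest_cluster))
}

subj_files <- list.files(file.path("results", "cohort"),
                         pattern = "^(control|disease)_.*\\.csv$",
                         full.names = TRUE)
rows <- lapply(subj_files, function(f) {
  group <- sub("_.*", "", basename(f))
  m <- read_matrix(f, group = group)
  mt <- threshold_proportional(normalize_matrix(m), 0.10)
  gq <- global_quantifiers(mt, seed = seed)
  cbind(data.frame(subject = sub("\\.csv$", "", basename(f)), group = group),
        as.data.frame(gq))
})
subj <- do.call(rbind, rows)
write.csv(subj, file.path("results", "subject_global.csv"), row.names = FALSE)
cat(sprintf("wrote per-subject global quantifiers for %d subjects\n", nrow(subj)))
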