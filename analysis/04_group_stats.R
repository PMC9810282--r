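#!/usr/bin/env Rscript
# Wilcoxon rank-sum comparison of per-subject global quantifiers between
# groups, with effect sizes r = |z|/sqrt(n). Reads results/subject_global.csv
# (run 03_quantify.R first). P-values are uncorrected; one row per quantifier.

suppressPackageStartupMessages(library(percnet))

subj <- read.csv(file.path("results", "subject_global.csv"))
metrics <- setdiff(names(subj), c("subject", "group"))
cmp <- compare_quantifiers(subj[subj$group == "control", metrics],
                           subj[subj$group == "disease", metrics])
write.csv(cmp, file.path("results", "group_comparison.csv"), row.names = FALSE)

cat("group comparison (mean +/- SE, control vs disease):\n")
for (i in seq_len(nrow(cmp))) {
  with(cmp[i, ], cat(sprintf(
    "  %-20s %8.3f +/- %.3f vs %8.3f +/- %.3f   p = %.4f  r = %.3f\n",
    metric, mean_a, se_a, mean_b, se_b, p, r)))
}
sig <- cmp$metric[cmp$p < 0.05]
cat(if (length(sig)) paste("significant at p < 0.05:", paste(sig, collapse = ", "))
    else "no quantifier significant at p < 0.05", "\n")
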