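#!/usr/bin/env Rscript
# Peak QC and content summaries: drop features missing in more than half
# the replicates of every group, count per-group detections and their
# overlap, and test the total-content trend along the pH gradient.

library(rhizometab)

ds <- read_dataset("results/data")
mf <- filter_by_missing_rate(ds$matrix, ds$samples, threshold = 0.5)
cat("Missing-rate filter: ", nrow(ds$matrix), " -> ", nrow(mf),
    " features (", length(attr(mf, "removed")), " removed)\n", sep = "")

det <- detection_summary(mf, ds$samples, min_detect = 1)
cat("Detected per group: ", paste(det$group_counts, collapse = " / "),
    "; shared ", det$shared_count, " (",
    sprintf("%.2f%%", det$min_shared_percent), " of the largest group)\n",
    sep = "")
write.table(data.frame(region = names(det$venn), count = det$venn),
            "results/venn.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

tot <- content_totals(mf, ds$samples, impute = "half-min")
cat("Group mean total content:\n")
print(tot$per_group, digits = 4)
cat("One-way ANOVA on per-sample totals: p =", signif(tot$p_value, 3), "\n")
write.table(tot$per_sample, "results/totals.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
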