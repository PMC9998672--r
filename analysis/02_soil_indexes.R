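#!/usr/bin/env Rscript
# Soil/microbial index summaries: per-group means of the nine indexes and
# their pairwise correlation matrix with significance stars. On this
# design every index rises with pH except the fungal count, so the
# expected sign pattern is all-positive among the eight co-varying
# indexes and all-negative against fungi.

library(rhizometab)

ds <- read_dataset("results/data")
idx <- ds$indexes

vars <- setdiff(names(idx), c("sample_id", "group_id", "replicate"))
gm <- aggregate(idx[vars], list(group = idx$group_id), mean)
cat("Per-group index means:\n")
print(gm, digits = 4)

ic <- index_correlation_matrix(idx, method = "pearson")
long <- as.data.frame(ic)
dir.create("results", showWarnings = FALSE)
write.table(long, "results/index_corr.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

fungi_rows <- long[long$var1 == "fungi" | long$var2 == "fungi", ]
other_rows <- long[long$var1 != "fungi" & long$var2 != "fungi", ]
cat("\nCorrelations among non-fungi indexes: ",
    sum(other_rows$r > 0), "/", nrow(other_rows), " positive\n", sep = "")
cat("Correlations involving fungi: ",
    sum(fungi_rows$r < 0), "/", nrow(fungi_rows), " negative\n", sep = "")
cat("Significant at P < 0.05: ", sum(long$stars != ""), "/", nrow(long),
    " pairs -> results/index_corr.tsv\n", sep = "")
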