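#!/usr/bin/env Rscript
# One-shot orchestration: run every stage on the generated dataset and
# emit the machine-readable report (stage TSVs + report.json), plus the
# PCA ordination summary.

library(rhizometab)

ds <- read_dataset("results/data")
rep_ <- run_pipeline(ds, out_dir = "results/pipeline", seed = 20230224)

cat("Screen: ", rep_$screen$n_positive, " positive / ",
    rep_$screen$n_negative, " negative / ", rep_$screen$n_conflicted,
    " conflicted (", rep_$screen$n_significant_metabolites,
    " significant metabolites)\n", sep = "")
cat("Characteristic: ", rep_$characteristic$n_total, " compounds, ",
    rep_$characteristic$n_categories, " categories\n", sep = "")
cat("PCA variance explained (first 3): ",
    paste(sprintf("%.1f%%", 100 * rep_$pca$var_explained[1:3]),
          collapse = ", "), "\n", sep = "")
cat("Report: results/pipeline/report.json\n")
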