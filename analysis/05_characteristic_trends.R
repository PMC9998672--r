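#!/usr/bin/env Rscript
# Characteristic compounds and trend classes: rank each signed set by
# content and keep the smallest prefix covering 90% of the set's total
# content; classify per-category content trends across the ordered pH
# groups at both taxonomy levels.

library(rhizometab)

ds <- read_dataset("results/data")
mf <- filter_by_missing_rate(ds$matrix, ds$samples)
recs <- correlate_all(ds$indexes, mf)
part <- partition_significant(recs)

sel_pos <- select_characteristic(mf, part$positive_set, coverage = 0.90)
sel_neg <- select_characteristic(mf, part$negative_set, coverage = 0.90)
cat("Characteristic compounds: ", length(sel_pos$selected), " of ",
    length(part$positive_set), " positive (",
    sprintf("%.1f%%", 100 * sel_pos$achieved_share), " of content); ",
    length(sel_neg$selected), " of ", length(part$negative_set),
    " negative (", sprintf("%.1f%%", 100 * sel_neg$achieved_share),
    ")\n", sep = "")
write.table(sel_pos$table, "results/characteristic_pos.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sel_neg$table, "results/characteristic_neg.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

rep_ <- characteristic_report(sel_pos, sel_neg, ds$annotations, mf,
                              ds$samples)
cat("Merged set: ", rep_$counts$n_total, " compounds in ",
    rep_$counts$n_categories, " secondary categories (",
    rep_$counts$categories_up, " rising, ", rep_$counts$categories_down,
    " falling)\n", sep = "")
write.table(rep_$compounds, "results/characteristic_merged.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

for (lv in c("superclass", "class")) {
  tab <- aggregate_by_category(mf, ds$annotations, ds$samples, level = lv)
  cat(lv, " level: ", nrow(tab), " categories; trends: ", sep = "")
  print(table(tab$trend))
  write.table(tab, sprintf("results/category_trends_%s.tsv", lv),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
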