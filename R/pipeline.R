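#' PCA ordination of samples from the metabolite matrix
#'
#' Singular value decomposition of the centered sample x feature table.
#' By default intensities are imputed and log-transformed (log(x + 1))
#' before centering, the usual stabilisation for LC-MS peak areas; set
#' `log_transform = FALSE` for the raw scale and `scale. = TRUE` for
#' unit-variance features.
#'
#' @param m Intensity matrix (features x samples).
#' @param scale. Unit-scale features (zero-variance features dropped first).
#' @param log_transform Apply log(x + 1) after imputation.
#' @param impute Imputation mode.
#' @return List of class `pca_result`: `scores` (samples x components),
#'   `var_explained` (fractions, non-increasing), `sdev`.
#' @export
pca_scores <- function(m, scale. = FALSE, log_transform = TRUE,
                       impute = "half-min") {
  if (ncol(m) < 2) stop("need at least 2 samples", call. = FALSE)
  x <- t(impute_missing(m, impute))
  if (log_transform) x <- log1p(x)
  v <- apply(x, 2, stats::sd)
  if (all(v == 0)) stop("degenerate input: all features constant", call. = FALSE)
  if (scale.) x <- x[, v > 0, drop = FALSE]
  pc <- stats::prcomp(x, center = TRUE, scale. = scale.)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x, var_explained = ve, sdev = pc$sdev),
            class = "pca_result")
}

#' Run the full screening pipeline on one dataset
#'
#' Executes QC filtering, detection overlap, content totals, the
#' index-metabolite correlation screen with signed partitioning, network
#' construction, characteristic-compound selection for both signed sets,
#' category trend classification at both taxonomy levels, and PCA; then
#' assembles a structured report whose counts all equal the stage outputs.
#' With `out_dir` set, every stage table is written as TSV, the network
#' as GraphML + SIF, and the report as `report.json` with a stable key
#' order, so identical inputs give byte-identical outputs.
#'
#' @param dataset List with `samples`, `indexes`, `matrix`, `annotations`
#'   (as from [simulate_dataset()] or [read_dataset()]).
#' @param out_dir Optional output directory.
#' @param alpha Significance level for the screen.
#' @param coverage Characteristic-set cumulative-share threshold.
#' @param method Correlation method.
#' @param correction `"none"` or `"bh"`.
#' @param impute Imputation mode.
#' @param rule Consensus rule for [partition_significant()].
#' @param threshold,filter_scope Missing-rate filter settings.
#' @param min_detect Detection threshold (replicates).
#' @param seed Seed recorded in provenance (the pipeline itself is
#'   deterministic given its inputs).
#' @return List of class `pipeline_report` with elements `detection`,
#'   `totals`, `screen`, `characteristic`, `trends`, `pca`, `provenance`,
#'   plus the full `stage` objects (not serialised into the JSON report).
#' @export
run_pipeline <- function(dataset, out_dir = NULL, alpha = 0.05,
                         coverage = 0.90, method = "pearson",
                         correction = "none", impute = "half-min",
                         rule = "unanimity", threshold = 0.5,
                         filter_scope = "all", min_detect = 1,
                         seed = NULL) {
  m0 <- dataset$matrix
  samples <- dataset$samples
  ann <- dataset$annotations

  mf <- filter_by_missing_rate(m0, samples, threshold = threshold,
                               scope = filter_scope)
  det <- detection_summary(mf, samples, min_detect = min_detect)
  tot <- content_totals(mf, samples, impute = impute)
  recs <- correlate_all(dataset$indexes, mf, method = method, alpha = alpha,
                        correction = correction)
  part <- partition_significant(recs, rule = rule)
  net <- build_network(part, annotations = ann)

  sel_pos <- if (length(part$positive_set)) {
    select_characteristic(mf, part$positive_set, coverage, impute)
  } else NULL
  sel_neg <- if (length(part$negative_set)) {
    select_characteristic(mf, part$negative_set, coverage, impute)
  } else NULL
  empty_set <- structure(list(selected = character(0), table = NULL,
                              achieved_share = NA_real_, coverage = coverage),
                         class = "characteristic_set")
  rep_char <- characteristic_report(sel_pos %||% empty_set,
                                    sel_neg %||% empty_set,
                                    ann, mf, samples, impute = impute,
                                    alpha = alpha)

  tr_super <- aggregate_by_category(mf, ann, samples, level = "superclass",
                                    impute = impute, alpha = alpha)
  tr_class <- aggregate_by_category(mf, ann, samples, level = "class",
                                    impute = impute, alpha = alpha)
  pca <- pca_scores(mf, impute = impute)

  trend_counts <- function(tab) {
    pats <- c("UP", "DOWN", "UP_DOWN", "DOWN_UP", "FLAT")
    as.list(stats::setNames(vapply(pats, function(p) sum(tab$trend == p),
                                   integer(1)), pats))
  }
  n_sig_met <- length(part$positive_set) + length(part$negative_set) +
    length(part$conflicted_set)

  report <- list(
    detection = list(
      group_counts = as.list(det$group_counts),
      shared_count = det$shared_count,
      union_count = det$union_count,
      min_shared_percent = det$min_shared_percent
    ),
    totals = list(
      per_group_mean = stats::setNames(as.list(tot$per_group$mean),
                                       tot$per_group$group_id),
      p_value = tot$p_value
    ),
    screen = list(
      n_features_tested = length(unique(recs$metabolite_id)),
      n_records = nrow(recs),
      n_significant_records = sum(recs$significant),
      n_significant_metabolites = n_sig_met,
      n_positive = length(part$positive_set),
      n_negative = length(part$negative_set),
      n_conflicted = length(part$conflicted_set),
      n_network_edges = nrow(net$edges)
    ),
    characteristic = list(
      n_positive_selected = rep_char$counts$n_positive,
      n_negative_selected = rep_char$counts$n_negative,
      n_total = rep_char$counts$n_total,
      n_categories = rep_char$counts$n_categories,
      categories_up = rep_char$counts$categories_up,
      categories_down = rep_char$counts$categories_down,
      achieved_share_positive = if (is.null(sel_pos)) NA else sel_pos$achieved_share,
      achieved_share_negative = if (is.null(sel_neg)) NA else sel_neg$achieved_share
    ),
    trends = list(
      superclass = c(list(n_categories = nrow(tr_super)), trend_counts(tr_super)),
      class = c(list(n_categories = nrow(tr_class)), trend_counts(tr_class))
    ),
    pca = list(
      var_explained = round(utils::head(pca$var_explained, 5), 10)
    ),
    provenance = list(
      package_version = as.character(utils::packageVersion("rhizometab")),
      seed = seed,
      config = list(alpha = alpha, coverage = coverage, method = method,
                    correction = correction, impute = impute, rule = rule,
                    threshold = threshold, filter_scope = filter_scope,
                    min_detect = min_detect)
    )
  )

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_tsv(as.data.frame(recs), file.path(out_dir, "screen.tsv"))
    part_df <- data.frame(
      metabolite_id = c(part$positive_set, part$negative_set,
                        part$conflicted_set),
      set = rep(c("positive", "negative", "conflicted"),
                c(length(part$positive_set), length(part$negative_set),
                  length(part$conflicted_set))),
      stringsAsFactors = FALSE
    )
    write_tsv(part_df, file.path(out_dir, "partition.tsv"))
    venn_df <- data.frame(region = names(det$venn %||% integer(0)),
                          count = as.integer(det$venn %||% integer(0)),
                          stringsAsFactors = FALSE)
    write_tsv(venn_df, file.path(out_dir, "venn.tsv"))
    write_tsv(tot$per_sample, file.path(out_dir, "totals.tsv"))
    write_network(net, graphml = file.path(out_dir, "network.graphml"),
                  sif = file.path(out_dir, "network.sif"))
    if (!is.null(sel_pos)) {
      write_tsv(sel_pos$table, file.path(out_dir, "characteristic_pos.tsv"))
    }
    if (!is.null(sel_neg)) {
      write_tsv(sel_neg$table, file.path(out_dir, "characteristic_neg.tsv"))
    }
    write_tsv(rep_char$compounds, file.path(out_dir, "characteristic_merged.tsv"))
    write_tsv(tr_super, file.path(out_dir, "category_trends_superclass.tsv"))
    write_tsv(tr_class, file.path(out_dir, "category_trends_class.tsv"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  }

  report$stage <- list(filtered = mf, detection = det, totals = tot,
                       records = recs, partition = part, network = net,
                       characteristic_pos = sel_pos,
                       characteristic_neg = sel_neg,
                       characteristic = rep_char,
                       trends_superclass = tr_super, trends_class = tr_class,
                       pca = pca)
  class(report) <- "pipeline_report"
  report
}
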