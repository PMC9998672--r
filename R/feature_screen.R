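#' Select characteristic compounds by cumulative content share
#'
#' Ranks the compounds of a signed correlated set by total content (mean
#' imputed intensity over all samples, descending; ties broken
#' lexicographically by id) and returns the smallest prefix whose
#' cumulative content share reaches the coverage threshold — the
#' content-dominant "characteristic" compounds of the set.
#'
#' @param m Intensity matrix (all samples).
#' @param ids Metabolite ids of the source set (e.g. the positive set of
#'   a [partition_significant()] result).
#' @param coverage Cumulative-share threshold in `(0, 1]` (default 0.90).
#' @param impute Imputation mode for [impute_missing()].
#' @return List of class `characteristic_set`: `selected` (ids in rank
#'   order), `table` (id, content, share, cumulative_share for the whole
#'   source set), `achieved_share`, `coverage`.
#' @export
select_characteristic <- function(m, ids, coverage = 0.90,
                                  impute = "half-min") {
  if (coverage <= 0 || coverage > 1) {
    stop("invalid config: coverage must be in (0, 1]", call. = FALSE)
  }
  empty <- structure(
    list(selected = character(0),
         table = data.frame(metabolite_id = character(0), content = numeric(0),
                            share = numeric(0), cumulative_share = numeric(0),
                            selected = logical(0), stringsAsFactors = FALSE),
         achieved_share = NA_real_, coverage = coverage),
    class = "characteristic_set")
  if (length(ids) == 0) {
    warning("empty source set: no characteristic compounds selected")
    return(empty)
  }
  missing_ids <- setdiff(ids, rownames(m))
  if (length(missing_ids)) {
    stop("unknown metabolite id(s): ", paste(utils::head(missing_ids, 3),
                                             collapse = ", "), call. = FALSE)
  }
  mi <- impute_missing(m[ids, , drop = FALSE], impute)
  content <- rowMeans(mi, na.rm = TRUE)
  ord <- order(-content, names(content))
  content <- content[ord]
  total <- sum(content)
  if (total <= 0) {
    warning("source set has zero total content")
    return(empty)
  }
  share <- content / total
  cum <- cumsum(share)
  k <- which(cum >= coverage)[1]
  tab <- data.frame(
    metabolite_id = names(content),
    content = unname(content),
    share = unname(share),
    cumulative_share = unname(cum),
    selected = seq_along(content) <= k,
    stringsAsFactors = FALSE
  )
  structure(
    list(selected = names(content)[seq_len(k)], table = tab,
         achieved_share = cum[[k]], coverage = coverage),
    class = "characteristic_set"
  )
}

#' Classify the trend of a quantity across three ordered pH groups
#'
#' Labels the shape of the ordered group means: `UP` (strictly
#' increasing), `DOWN` (strictly decreasing), `UP_DOWN` (peak in the
#' middle group), `DOWN_UP` (trough in the middle group), or `FLAT` on
#' any tie (within relative tolerance). When replicate values and group
#' labels are supplied, a one-way group test marks whether group means
#' differ significantly; the pattern label is retained either way.
#'
#' @param group_means Numeric vector of exactly 3 means, in group order.
#' @param replicate_values Optional per-sample values for the test.
#' @param groups Group labels aligned with `replicate_values`.
#' @param alpha Significance level for the group test.
#' @param test `"anova"` or `"kruskal"`.
#' @param tol Relative tolerance for tie detection (default 1e-9).
#' @return List of class `trend`: `pattern`, `p_value`, `significant`.
#' @export
classify_trend <- function(group_means, replicate_values = NULL,
                           groups = NULL, alpha = 0.05,
                           test = c("anova", "kruskal"), tol = 1e-9) {
  test <- match.arg(test)
  if (length(group_means) != 3) {
    stop("invalid input: exactly 3 ordered group means required", call. = FALSE)
  }
  m <- as.numeric(group_means)
  eps <- tol * max(abs(m), 1e-300)
  eq <- function(a, b) abs(a - b) <= eps
  pattern <- if (eq(m[1], m[2]) || eq(m[2], m[3]) || eq(m[1], m[3])) {
    "FLAT"
  } else if (m[1] < m[2] && m[2] < m[3]) {
    "UP"
  } else if (m[1] > m[2] && m[2] > m[3]) {
    "DOWN"
  } else if (m[2] > max(m[1], m[3])) {
    "UP_DOWN"
  } else {
    "DOWN_UP"
  }
  p <- NA_real_
  if (!is.null(replicate_values) && !is.null(groups)) {
    df <- data.frame(y = replicate_values, g = factor(groups))
    if (nlevels(df$g) > 1 && stats::sd(df$y) > 0) {
      p <- if (test == "anova") {
        summary(stats::aov(y ~ g, data = df))[[1]][["Pr(>F)"]][1]
      } else {
        stats::kruskal.test(y ~ g, data = df)$p.value
      }
    }
  }
  structure(list(pattern = pattern, p_value = p,
                 significant = if (is.na(p)) NA else p < alpha),
            class = "trend")
}

#' Aggregate metabolite content by taxonomy category and classify trends
#'
#' Sums member intensities per category and sample, then classifies each
#' category's per-group mean content trend along the ordered gradient
#' (with a one-way group test on the per-sample category totals).
#'
#' @param m Intensity matrix.
#' @param annotations Annotation table (`metabolite_id`, `superclass`,
#'   `class`).
#' @param samples Sample metadata.
#' @param level `"superclass"` (primary) or `"class"` (secondary).
#' @param impute Imputation mode.
#' @param alpha,test Passed to [classify_trend()].
#' @param drop_unannotated If `FALSE` (default), an unannotated matrix row
#'   is an error; if `TRUE` such rows are dropped.
#' @return Data frame, one row per category (alphabetical): `category`,
#'   `n_members`, one `mean_<group>` column per group, `trend`,
#'   `p_value`, `significant`.
#' @export
aggregate_by_category <- function(m, annotations, samples,
                                  level = c("superclass", "class"),
                                  impute = "half-min", alpha = 0.05,
                                  test = "anova", drop_unannotated = FALSE) {
  level <- match.arg(level)
  g <- sample_groups(m, samples)
  lab <- annotations[[level]][match(rownames(m), annotations$metabolite_id)]
  if (anyNA(lab)) {
    if (drop_unannotated) {
      keep <- !is.na(lab)
      m <- m[keep, , drop = FALSE]
      lab <- lab[keep]
    } else {
      stop("unannotated feature(s) present; set drop_unannotated = TRUE to drop",
           call. = FALSE)
    }
  }
  mi <- impute_missing(m, impute)
  cats <- sort(unique(lab))
  lvs <- levels(g)
  rows <- lapply(cats, function(ct) {
    totals <- colSums(mi[lab == ct, , drop = FALSE], na.rm = TRUE)
    means <- vapply(lvs, function(lv) mean(totals[g == lv]), numeric(1))
    tr <- if (length(lvs) == 3) {
      classify_trend(means, totals, g, alpha = alpha, test = test)
    } else {
      list(pattern = NA_character_, p_value = NA_real_, significant = NA)
    }
    out <- data.frame(category = ct, n_members = sum(lab == ct),
                      stringsAsFactors = FALSE)
    for (i in seq_along(lvs)) out[[paste0("mean_", lvs[i])]] <- means[i]
    out$trend <- tr$pattern
    out$p_value <- tr$p_value
    out$significant <- tr$significant
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Merge the signed characteristic sets into one annotated report
#'
#' Combines the characteristic compounds derived from the positively and
#' negatively correlated sets (disjoint by construction; overlap is an
#' integrity error), annotates them, aggregates by secondary class, and
#' counts categories trending up versus down along the gradient.
#'
#' @param pos_set,neg_set `characteristic_set` objects from
#'   [select_characteristic()].
#' @param annotations Annotation table.
#' @param m Intensity matrix (for category trend classification).
#' @param samples Sample metadata.
#' @param impute,alpha,test Passed through to [aggregate_by_category()].
#' @return List of class `characteristic_report`: `compounds` (per-
#'   compound table with `source_set`), `categories` (per-class table as
#'   [aggregate_by_category()]), and `counts` (n_positive, n_negative,
#'   n_total, n_categories, categories_up, categories_down,
#'   categories_other).
#' @export
characteristic_report <- function(pos_set, neg_set, annotations, m, samples,
                                  impute = "half-min", alpha = 0.05,
                                  test = "anova") {
  pos_ids <- pos_set$selected
  neg_ids <- neg_set$selected
  if (length(intersect(pos_ids, neg_ids))) {
    stop("integrity error: characteristic sets overlap", call. = FALSE)
  }
  ids <- c(pos_ids, neg_ids)
  compounds <- data.frame(
    metabolite_id = ids,
    source_set = rep(c("positive", "negative"),
                     c(length(pos_ids), length(neg_ids))),
    stringsAsFactors = FALSE
  )
  ai <- match(compounds$metabolite_id, annotations$metabolite_id)
  compounds$name <- annotations$name[ai]
  compounds$superclass <- annotations$superclass[ai]
  compounds$class <- annotations$class[ai]

  categories <- if (length(ids)) {
    aggregate_by_category(m[ids, , drop = FALSE], annotations, samples,
                          level = "class", impute = impute, alpha = alpha,
                          test = test)
  } else {
    data.frame(category = character(0), n_members = integer(0),
               trend = character(0), stringsAsFactors = FALSE)
  }
  n_up <- sum(categories$trend == "UP", na.rm = TRUE)
  n_down <- sum(categories$trend == "DOWN", na.rm = TRUE)
  structure(
    list(compounds = compounds, categories = categories,
         counts = list(
           n_positive = length(pos_ids), n_negative = length(neg_ids),
           n_total = length(ids), n_categories = nrow(categories),
           categories_up = n_up, categories_down = n_down,
           categories_other = nrow(categories) - n_up - n_down)),
    class = "characteristic_report"
  )
}
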