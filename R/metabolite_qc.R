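sample_groups <- function(m, samples) {
  if (!setequal(colnames(m), samples$sample_id) ||
      ncol(m) != nrow(samples)) {
    stop("alignment error: matrix columns and sample metadata disagree",
         call. = FALSE)
  }
  g <- samples$group_id[match(colnames(m), samples$sample_id)]
  droplevels(as.factor(g))
}

group_missing_rates <- function(m, g) {
  out <- vapply(levels(g), function(lv) {
    rowMeans(is.na(m[, g == lv, drop = FALSE]))
  }, numeric(nrow(m)))
  matrix(out, nrow = nrow(m), dimnames = list(rownames(m), levels(g)))
}

#' Filter features by within-group missing rate
#'
#' A feature is removed when its fraction of missing cells exceeds the
#' threshold (strict `>`) in *every* group, so a peak reliably present in
#' any one group is kept. `scope = "any"` implements the stricter
#' alternative reading (drop when any group exceeds the threshold).
#'
#' @param m Intensity matrix (features x samples, `NA` = missing).
#' @param samples Sample metadata with `sample_id`, `group_id`.
#' @param threshold Missing-rate threshold in `[0, 1]` (default 0.5).
#' @param scope `"all"` (default) or `"any"`.
#' @return The filtered matrix; removed feature ids in
#'   `attr(, "removed")`.
#' @export
filter_by_missing_rate <- function(m, samples, threshold = 0.5,
                                   scope = c("all", "any")) {
  scope <- match.arg(scope)
  if (threshold < 0 || threshold > 1) {
    stop("invalid config: threshold must be in [0, 1]", call. = FALSE)
  }
  g <- sample_groups(m, samples)
  if (nrow(m) == 0) {
    attr(m, "removed") <- character(0)
    return(m)
  }
  rates <- group_missing_rates(m, g)
  drop <- if (scope == "all") {
    apply(rates > threshold, 1, all)
  } else {
    apply(rates > threshold, 1, any)
  }
  out <- m[!drop, , drop = FALSE]
  attr(out, "removed") <- rownames(m)[drop]
  out
}

#' Detection overlap across groups (Venn summary)
#'
#' A feature counts as detected in a group when observed (non-missing) in
#' at least `min_detect` replicates. For a three-group design all seven
#' Venn regions are reported; the shared percentage divides the
#' all-groups-shared count by the *largest* per-group count, i.e. the
#' conservative minimum.
#'
#' @param m Intensity matrix.
#' @param samples Sample metadata.
#' @param min_detect Minimum observed replicates for detection (default 1).
#' @return A list of class `detection_summary`: `group_counts`, `venn`
#'   (named region counts, exclusive regions), `shared_count`,
#'   `union_count`, `min_shared_percent`, and the per-group detected id
#'   sets in `detected`.
#' @export
detection_summary <- function(m, samples, min_detect = 1) {
  g <- sample_groups(m, samples)
  lvs <- levels(g)
  detected <- lapply(lvs, function(lv) {
    obs <- rowSums(!is.na(m[, g == lv, drop = FALSE]))
    rownames(m)[obs >= min_detect]
  })
  names(detected) <- lvs
  counts <- lengths(detected)
  shared <- Reduce(intersect, detected)
  un <- Reduce(union, detected)

  venn <- NULL
  if (length(lvs) == 3) {
    inset <- vapply(detected, function(s) un %in% s, logical(length(un)))
    if (length(un) == 0) inset <- matrix(logical(0), 0, 3)
    key <- apply(inset, 1, function(z) paste(lvs[z], collapse = "&"))
    labels <- c(lvs,
                paste(lvs[c(1, 1, 2)], lvs[c(2, 3, 3)], sep = "&"),
                paste(lvs, collapse = "&"))
    venn <- vapply(labels, function(lb) sum(key == lb), integer(1))
  }

  structure(
    list(group_counts = counts, detected = detected, venn = venn,
         shared_count = length(shared), union_count = length(un),
         min_shared_percent = shared_percentage(counts, length(shared)),
         min_detect = min_detect),
    class = "detection_summary"
  )
}

#' Conservative shared-feature percentage
#'
#' 100 * shared / max(per-group detected counts): the smallest percentage
#' any single group's detected set has in common with all groups.
#'
#' @param group_counts Integer vector of per-group detected counts.
#' @param shared Count of features detected in every group.
#' @return Percentage (0-100); `NA` when all counts are zero.
#' @export
shared_percentage <- function(group_counts, shared) {
  mx <- max(group_counts)
  if (mx == 0) return(NA_real_)
  100 * shared / mx
}

#' Impute missing intensities
#'
#' Default `"half-min"` replaces a feature's missing cells with half of
#' that feature's minimum observed value (standard LC-MS practice for
#' values below the detection limit); `"zero"` uses 0; `"none"` leaves
#' `NA` in place. A fully missing feature is imputed as 0.
#'
#' @param m Intensity matrix.
#' @param method `"half-min"`, `"zero"` or `"none"`.
#' @return Matrix with missing cells replaced (unless `"none"`).
#' @export
impute_missing <- function(m, method = c("half-min", "zero", "none")) {
  method <- match.arg(method)
  if (method == "none" || !anyNA(m)) return(m)
  if (method == "zero") {
    m[is.na(m)] <- 0
    return(m)
  }
  fill <- apply(m, 1, function(v) {
    if (all(is.na(v))) 0 else min(v, na.rm = TRUE) / 2
  })
  na_idx <- which(is.na(m), arr.ind = TRUE)
  m[na_idx] <- fill[na_idx[, 1]]
  m
}

#' Per-sample and per-group total metabolite content
#'
#' "Content" is the column sum of (imputed) peak areas — relative, not
#' normalised by sample mass. A one-way group test on the per-sample
#' totals quantifies the content trend along the gradient.
#'
#' @param m Intensity matrix (filtered).
#' @param samples Sample metadata.
#' @param impute Imputation mode passed to [impute_missing()]; `"none"`
#'   sums observed cells only.
#' @param test `"anova"` (default) or `"kruskal"`.
#' @return List: `per_sample` (sample_id, group_id, total), `per_group`
#'   (group_id, mean, sd, n), `p_value`.
#' @export
content_totals <- function(m, samples, impute = "half-min",
                           test = c("anova", "kruskal")) {
  test <- match.arg(test)
  g <- sample_groups(m, samples)
  mi <- impute_missing(m, impute)
  totals <- colSums(mi, na.rm = TRUE)
  per_sample <- data.frame(
    sample_id = colnames(m),
    group_id = g,
    total = unname(totals),
    stringsAsFactors = FALSE
  )
  per_group <- do.call(rbind, lapply(levels(g), function(lv) {
    v <- per_sample$total[g == lv]
    data.frame(group_id = lv, mean = mean(v), sd = stats::sd(v),
               n = length(v), stringsAsFactors = FALSE)
  }))
  p <- if (nlevels(g) > 1 && all(table(g) > 0) && stats::sd(totals) > 0) {
    if (test == "anova") {
      summary(stats::aov(total ~ group_id, data = per_sample))[[1]][["Pr(>F)"]][1]
    } else {
      stats::kruskal.test(total ~ group_id, data = per_sample)$p.value
    }
  } else NA_real_
  list(per_sample = per_sample, per_group = per_group, p_value = p)
}
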