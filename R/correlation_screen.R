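index_columns <- function(tbl) {
  setdiff(names(tbl), c("sample_id", "group_id", "replicate"))
}

#' Correlate every soil index with every metabolite
#'
#' Computes one correlation per (index, metabolite) pair across samples
#' at replicate level, with two-sided p-values from the t approximation
#' (Spearman correlates ranks the same way). Missing metabolite cells use
#' pairwise-complete observations; pairs with fewer than 3 complete
#' observations or a constant metabolite are skipped with a logged reason.
#' Benjamini-Hochberg adjusted p-values over all computed pairs are
#' reported alongside; significance is called on the raw p at `alpha`
#' (the conventional per-test threshold for correlation stars).
#'
#' @param index_table Per-sample index table (must share sample ids with
#'   the matrix).
#' @param m Intensity matrix (features x samples).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param alpha Per-test significance level (default 0.05).
#' @param correction `"none"` (default: significance on raw p) or `"bh"`
#'   (significance on the BH-adjusted p).
#' @return Data frame of class `screen_records`, ordered by index then
#'   metabolite id: `index`, `metabolite_id`, `n`, `r`, `p`, `p_adj`,
#'   `significant`, `sign`. Skipped pairs are listed in
#'   `attr(, "skipped")`; `alpha` and `method` are attributes.
#' @export
correlate_all <- function(index_table, m, method = c("pearson", "spearman"),
                          alpha = 0.05, correction = c("none", "bh")) {
  method <- match.arg(method)
  correction <- match.arg(correction)
  if (!setequal(index_table$sample_id, colnames(m))) {
    stop("alignment error: sample ids differ between index table and matrix",
         call. = FALSE)
  }
  idx <- index_table[match(colnames(m), index_table$sample_id), , drop = FALSE]
  vars <- index_columns(idx)

  mm <- m
  if (method == "spearman") {
    mm <- t(apply(m, 1, rank, na.last = "keep"))
    dimnames(mm) <- dimnames(m)
    if (nrow(m) == 1) mm <- matrix(mm, nrow = 1, dimnames = dimnames(m))
  }
  n_obs <- rowSums(!is.na(mm))
  row_sd <- apply(mm, 1, stats::sd, na.rm = TRUE)
  usable <- n_obs >= 3 & !is.na(row_sd) & row_sd > 0
  skipped <- data.frame(
    metabolite_id = rownames(m)[!usable],
    reason = ifelse(n_obs[!usable] < 3, "fewer than 3 observations",
                    "constant intensity"),
    stringsAsFactors = FALSE
  )

  mu <- mm[usable, , drop = FALSE]
  nu <- n_obs[usable]
  recs <- vector("list", length(vars))
  for (k in seq_along(vars)) {
    x <- idx[[vars[k]]]
    if (method == "spearman") x <- rank(x)
    r <- if (nrow(mu)) drop(stats::cor(x, t(mu), use = "pairwise.complete.obs")) else numeric(0)
    r <- pmin(pmax(r, -1), 1)
    tt <- r * sqrt((nu - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = nu - 2)
    p[abs(r) == 1] <- 0
    recs[[k]] <- data.frame(
      index = vars[k],
      metabolite_id = rownames(mu),
      n = as.integer(nu),
      r = unname(r),
      p = unname(p),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, recs)
  out <- out[order(out$index, out$metabolite_id), , drop = FALSE]
  rownames(out) <- NULL
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- if (correction == "bh") out$p_adj < alpha else out$p < alpha
  out$sign <- ifelse(out$r >= 0, "+", "-")
  attr(out, "alpha") <- alpha
  attr(out, "method") <- method
  attr(out, "correction") <- correction
  attr(out, "skipped") <- skipped
  class(out) <- c("screen_records", class(out))
  out
}

#' Partition screened metabolites by consensus correlation sign
#'
#' Every metabolite significant for at least one index is partitioned into
#' a positive, negative or conflicted set. Because the fungal count runs
#' opposite to the other eight indexes along the gradient, fungi's sign is
#' inverted before sign comparison, so "positive" means positively
#' correlated with the pH-covarying indexes (equivalently negatively with
#' fungi). The default `"unanimity"` rule sends any metabolite whose
#' significant correlations disagree in (fungi-adjusted) sign to the
#' conflicted set; `"majority"` anchors on pH's sign when pH is
#' significant, otherwise takes the majority sign, with ties conflicted.
#'
#' @param records Output of [correlate_all()].
#' @param rule `"unanimity"` (default) or `"majority"`.
#' @param fungi_index Name of the index whose sign is inverted.
#' @param ph_index Name of the anchoring index for `"majority"`.
#' @return List of class `screen_result`: `positive_set`, `negative_set`,
#'   `conflicted_set` (sorted metabolite ids), `alpha`, `rule`, `records`.
#' @export
partition_significant <- function(records, rule = c("unanimity", "majority"),
                                  fungi_index = "fungi", ph_index = "ph") {
  rule <- match.arg(rule)
  sig <- records[records$significant, , drop = FALSE]
  adj_sign <- ifelse(sig$index == fungi_index,
                     ifelse(sig$sign == "+", "-", "+"), sig$sign)
  pos <- neg <- con <- character(0)
  for (id in unique(sig$metabolite_id)) {
    rows <- sig$metabolite_id == id
    s <- adj_sign[rows]
    verdict <- if (rule == "unanimity") {
      if (all(s == "+")) "+" else if (all(s == "-")) "-" else "conflict"
    } else {
      ph_row <- rows & sig$index == ph_index
      if (any(ph_row)) {
        adj_sign[ph_row][1]
      } else {
        np <- sum(s == "+"); nn <- sum(s == "-")
        if (np > nn) "+" else if (nn > np) "-" else "conflict"
      }
    }
    if (verdict == "+") pos <- c(pos, id)
    else if (verdict == "-") neg <- c(neg, id)
    else con <- c(con, id)
  }
  structure(
    list(positive_set = sort(pos), negative_set = sort(neg),
         conflicted_set = sort(con),
         alpha = attr(records, "alpha") %||% 0.05,
         rule = rule, records = records),
    class = "screen_result"
  )
}

#' @export
print.screen_result <- function(x, ...) {
  cat("Correlation screen (alpha = ", x$alpha, ", rule = ", x$rule, ")\n",
      "  positive: ", length(x$positive_set),
      "  negative: ", length(x$negative_set),
      "  conflicted: ", length(x$conflicted_set), "\n", sep = "")
  invisible(x)
}

#' Bipartite index-metabolite interaction network
#'
#' One edge per significant (index, metabolite) correlation among
#' partitioned metabolites (conflicted included — they are partitioned,
#' not dropped), signed by the correlation and weighted by |r|. Metabolite
#' nodes carry their superclass when annotations are supplied.
#'
#' @param screen A `screen_result` from [partition_significant()].
#' @param annotations Optional annotation table with `metabolite_id` and
#'   `superclass`.
#' @return List of class `interaction_network`: `edges` (data frame
#'   source, target, sign, weight) and `graph` (a bipartite
#'   [igraph::graph] with node attributes `type_label` and `superclass`).
#' @export
build_network <- function(screen, annotations = NULL) {
  kept <- c(screen$positive_set, screen$negative_set, screen$conflicted_set)
  sig <- screen$records[screen$records$significant &
                          screen$records$metabolite_id %in% kept, , drop = FALSE]
  edges <- data.frame(
    source = sig$index,
    target = sig$metabolite_id,
    sign = sig$sign,
    weight = abs(sig$r),
    stringsAsFactors = FALSE
  )
  rownames(edges) <- NULL
  idx_nodes <- sort(unique(edges$source))
  met_nodes <- sort(unique(edges$target))
  g <- igraph::graph_from_data_frame(
    edges,
    directed = FALSE,
    vertices = data.frame(
      name = c(idx_nodes, met_nodes),
      type = rep(c(FALSE, TRUE), c(length(idx_nodes), length(met_nodes))),
      type_label = rep(c("index", "metabolite"),
                       c(length(idx_nodes), length(met_nodes))),
      stringsAsFactors = FALSE
    )
  )
  if (!is.null(annotations)) {
    sc <- annotations$superclass[match(igraph::V(g)$name,
                                       annotations$metabolite_id)]
    sc[igraph::V(g)$type_label == "index"] <- NA
    g <- igraph::set_vertex_attr(g, "superclass", value = sc)
  }
  structure(list(edges = edges, graph = g), class = "interaction_network")
}

#' Export an interaction network as GraphML and SIF
#'
#' @param network An `interaction_network` from [build_network()].
#' @param graphml Path for the GraphML file (`NULL` to skip).
#' @param sif Path for the SIF file (`NULL` to skip); relations are
#'   `pos` / `neg`.
#' @return Invisibly, the paths written.
#' @export
write_network <- function(network, graphml = NULL, sif = NULL) {
  written <- character(0)
  if (!is.null(graphml)) {
    igraph::write_graph(network$graph, graphml, format = "graphml")
    written <- c(written, graphml)
  }
  if (!is.null(sif)) {
    rel <- ifelse(network$edges$sign == "+", "pos", "neg")
    lines <- paste(network$edges$source, rel, network$edges$target, sep = "\t")
    writeLines(lines, sif)
    written <- c(written, sif)
  }
  invisible(written)
}
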