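# TSV I/O. Numeric cells are printed with %.17g so doubles round-trip
# exactly; empty cell = missing.

fmt_num <- function(x) ifelse(is.na(x), NA_character_, sprintf("%.17g", x))

write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) out[[j]] <- fmt_num(out[[j]])
    if (is.factor(out[[j]])) out[[j]] <- as.character(out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path, numeric_cols = NULL) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = "", check.names = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
  for (nm in intersect(numeric_cols %||% character(0), names(df))) {
    df[[nm]] <- as.numeric(df[[nm]])
  }
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

matrix_to_df <- function(m) {
  df <- data.frame(metabolite_id = rownames(m), stringsAsFactors = FALSE)
  for (s in colnames(m)) df[[s]] <- m[, s]
  df
}

df_to_matrix <- function(df) {
  ids <- df$metabolite_id
  cols <- setdiff(names(df), "metabolite_id")
  m <- matrix(NA_real_, nrow = length(ids), ncol = length(cols),
              dimnames = list(ids, cols))
  for (s in cols) m[, s] <- as.numeric(df[[s]])
  m
}

truth_to_df <- function(truth) {
  data.frame(
    metabolite_id = c(truth$planted_positive, truth$planted_negative,
                      truth$null_set),
    role = rep(c("positive", "negative", "null"),
               c(length(truth$planted_positive),
                 length(truth$planted_negative),
                 length(truth$null_set))),
    stringsAsFactors = FALSE
  )
}

df_to_truth <- function(df) {
  list(planted_positive = df$metabolite_id[df$role == "positive"],
       planted_negative = df$metabolite_id[df$role == "negative"],
       null_set = df$metabolite_id[df$role == "null"])
}

#' Write a dataset to a directory of TSV files
#'
#' Writes `matrix.tsv` (rows = metabolite_id, columns = sample_id, empty
#' cell = missing), `samples.tsv`, `annotations.tsv`, `indexes.tsv` and
#' `truth.tsv` (when ground truth is present). Numeric values are written
#' with enough digits that [read_dataset()] restores them exactly, and
#' identical inputs produce identical bytes.
#'
#' @param dataset List as returned by [simulate_dataset()] (the `truth`
#'   element is optional).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) stop("cannot create directory: ", dir, call. = FALSE)
  }
  paths <- c(
    matrix = file.path(dir, "matrix.tsv"),
    samples = file.path(dir, "samples.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    indexes = file.path(dir, "indexes.tsv")
  )
  write_tsv(matrix_to_df(dataset$matrix), paths["matrix"])
  write_tsv(dataset$samples, paths["samples"])
  write_tsv(dataset$annotations, paths["annotations"])
  write_tsv(dataset$indexes, paths["indexes"])
  if (!is.null(dataset$truth)) {
    paths <- c(paths, truth = file.path(dir, "truth.tsv"))
    write_tsv(truth_to_df(dataset$truth), paths["truth"])
  }
  invisible(paths)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing the TSV files.
#' @return List with `samples`, `indexes`, `matrix`, `annotations` and,
#'   if present on disk, `truth`; group levels are restored as an ordered
#'   factor.
#' @export
read_dataset <- function(dir) {
  samples <- read_tsv(file.path(dir, "samples.tsv"))
  samples$replicate <- as.integer(samples$replicate)
  lev <- unique(samples$group_id)
  samples$group_id <- factor(samples$group_id, levels = lev, ordered = TRUE)

  idx_cols <- default_index_anchors()$index
  indexes <- read_tsv(file.path(dir, "indexes.tsv"), numeric_cols = idx_cols)
  indexes$replicate <- as.integer(indexes$replicate)
  indexes$group_id <- factor(indexes$group_id, levels = lev, ordered = TRUE)
  num_idx <- setdiff(names(indexes), c("sample_id", "group_id", "replicate"))
  for (nm in num_idx) indexes[[nm]] <- as.numeric(indexes[[nm]])

  mat_df <- read_tsv(file.path(dir, "matrix.tsv"))
  out <- list(
    samples = samples,
    indexes = indexes,
    matrix = df_to_matrix(mat_df),
    annotations = read_tsv(file.path(dir, "annotations.tsv"))
  )
  truth_path <- file.path(dir, "truth.tsv")
  if (file.exists(truth_path)) out$truth <- df_to_truth(read_tsv(truth_path))
  out
}
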