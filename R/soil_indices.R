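#' Microbial biomass carbon by chloroform fumigation-extraction
#'
#' MBC = (fumigated organic C - unfumigated organic C) / Kc, with the
#' standard conversion constant Kc = 0.38.
#'
#' @param c_fumigated Organic carbon in fumigated soil, mg C/kg.
#' @param c_unfumigated Organic carbon in unfumigated soil, mg C/kg.
#' @param kc Conversion constant (default 0.38).
#' @return Microbial biomass carbon, mg/kg. Vectorised.
#' @export
microbial_biomass_carbon <- function(c_fumigated, c_unfumigated, kc = 0.38) {
  if (any(c_fumigated < 0 | c_unfumigated < 0)) {
    stop("measurements must be non-negative", call. = FALSE)
  }
  if (any(c_fumigated < c_unfumigated)) {
    stop("measurement order error: fumigated carbon below unfumigated (swapped inputs?)",
         call. = FALSE)
  }
  (c_fumigated - c_unfumigated) / kc
}

#' Microbial biomass nitrogen by chloroform fumigation-extraction
#'
#' MBN = (fumigated total N - unfumigated total N) / Kn, with Kn = 0.54.
#'
#' @param n_fumigated Total nitrogen in fumigated soil, mg N/kg.
#' @param n_unfumigated Total nitrogen in unfumigated soil, mg N/kg.
#' @param kn Conversion constant (default 0.54).
#' @return Microbial biomass nitrogen, mg/kg. Vectorised.
#' @export
microbial_biomass_nitrogen <- function(n_fumigated, n_unfumigated, kn = 0.54) {
  if (any(n_fumigated < 0 | n_unfumigated < 0)) {
    stop("measurements must be non-negative", call. = FALSE)
  }
  if (any(n_fumigated < n_unfumigated)) {
    stop("measurement order error: fumigated nitrogen below unfumigated (swapped inputs?)",
         call. = FALSE)
  }
  (n_fumigated - n_unfumigated) / kn
}

#' Soil microbial respiration intensity
#'
#' CO2 evolved per kilogram of soil per hour.
#'
#' @param co2_mass CO2 released, mg.
#' @param soil_mass Soil mass, kg.
#' @param duration Incubation time, h.
#' @return Respiration intensity, mg CO2/kg.h.
#' @export
respiration_rate <- function(co2_mass, soil_mass, duration) {
  if (any(co2_mass < 0)) stop("CO2 mass must be non-negative", call. = FALSE)
  if (any(soil_mass <= 0) || any(duration <= 0)) {
    stop("soil mass and duration must be positive", call. = FALSE)
  }
  co2_mass / (soil_mass * duration)
}

star_code <- function(p, alpha_levels = c(0.05, 0.01)) {
  a <- sort(alpha_levels, decreasing = TRUE)  # c(0.05, 0.01)
  ifelse(is.na(p), "", ifelse(p < a[2], "**", ifelse(p < a[1], "*", "")))
}

#' Pairwise correlation matrix of the soil/microbial indexes
#'
#' Correlates every pair of index columns across samples (replicate level
#' by default), with two-sided p-values and significance stars at the
#' 0.05 / 0.01 levels. Constant columns yield undefined cells (`NA`),
#' recorded in the result rather than dropped silently.
#'
#' @param tbl Index table (data frame); non-index columns `sample_id`,
#'   `group_id`, `replicate` are ignored.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param alpha_levels Two significance thresholds for the star codes.
#' @param group_means If `TRUE`, correlate group means (n = number of
#'   groups) instead of replicate-level values; requires `group_id`.
#' @return An object of class `index_corr`: list with matrices `r`, `p`,
#'   `stars`, the sample size `n`, `method`, and `undefined` (names of
#'   constant columns, if any). `as.data.frame()` gives the long format.
#' @export
index_correlation_matrix <- function(tbl, method = c("pearson", "spearman"),
                                     alpha_levels = c(0.05, 0.01),
                                     group_means = FALSE) {
  method <- match.arg(method)
  vars <- setdiff(names(tbl), c("sample_id", "group_id", "replicate"))
  x <- tbl[vars]
  if (group_means) {
    if (is.null(tbl$group_id)) stop("group_means requires a group_id column", call. = FALSE)
    x <- aggregate(x, list(group_id = tbl$group_id), mean)[vars]
  }
  n <- nrow(x)
  if (n < 3) stop("insufficient data: need at least 3 samples", call. = FALSE)
  k <- length(vars)
  constant <- vars[vapply(x, function(v) stats::sd(v) == 0, logical(1))]
  if (length(constant)) {
    warning("constant column(s) with undefined correlations: ",
            paste(constant, collapse = ", "))
  }
  r <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  p <- r
  diag(r) <- 1
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (vars[i] %in% constant || vars[j] %in% constant) next
      ct <- suppressWarnings(
        stats::cor.test(x[[i]], x[[j]], method = method, exact = FALSE)
      )
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  structure(
    list(r = r, p = p, stars = matrix(star_code(p, alpha_levels), k, k,
                                      dimnames = list(vars, vars)),
         n = n, method = method, alpha_levels = alpha_levels,
         undefined = constant),
    class = "index_corr"
  )
}

#' @export
as.data.frame.index_corr <- function(x, ...) {
  vars <- rownames(x$r)
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  out <- data.frame(
    var1 = vars[idx[, 1]],
    var2 = vars[idx[, 2]],
    r = x$r[idx],
    p = x$p[idx],
    stars = x$stars[idx],
    stringsAsFactors = FALSE
  )
  out[order(out$var1, out$var2), , drop = FALSE]
}

#' @export
print.index_corr <- function(x, ...) {
  cat("Index correlation matrix (", x$method, ", n = ", x$n, ")\n", sep = "")
  print(round(x$r, 3))
  if (length(x$undefined)) {
    cat("undefined (constant) columns:", paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}
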