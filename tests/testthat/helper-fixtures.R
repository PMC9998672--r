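# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from disk.

# Minimal 3x3 design metadata.
toy_samples <- function(n_groups = 3, n_reps = 3) {
  grp <- paste0("P", seq_len(n_groups))
  data.frame(
    sample_id = paste0(rep(grp, each = n_reps), "_", seq_len(n_reps)),
    group_id = factor(rep(grp, each = n_reps), levels = grp, ordered = TRUE),
    replicate = rep(seq_len(n_reps), n_groups),
    stringsAsFactors = FALSE
  )
}

# Feature x sample matrix from a vector (row-major), with optional NA
# positions given as (row, col) pairs.
toy_matrix <- function(values, n_features, samples = toy_samples(),
                       na_cells = NULL) {
  m <- matrix(values, nrow = n_features, byrow = TRUE,
              dimnames = list(sprintf("met_%04d", seq_len(n_features)),
                              samples$sample_id))
  if (!is.null(na_cells)) m[na_cells] <- NA
  m
}

# A dataset with planted signed effects and negligible noise, used to
# exercise the screen against known truth.
planted_dataset <- function(seed = 7, n_pos = 55, n_neg = 166, n_null = 0,
                            noise_sd = 0.001, missing_rate = 0,
                            n_metabolites = n_pos + n_neg + n_null) {
  cfg <- sim_config(seed = seed, n_metabolites = n_metabolites,
                    n_pos = n_pos, n_neg = n_neg,
                    missing_rate = missing_rate, noise_sd = noise_sd)
  simulate_dataset(cfg)
}

# Monte-Carlo permutation p-value for |r| of one pair (the independent
# oracle; deliberately a plain loop, not the package's analytic path).
perm_pvalue <- function(x, y, n_perm = 10000) {
  robs <- abs(cor(x, y))
  hits <- 0L
  for (b in seq_len(n_perm)) {
    if (abs(cor(x, sample(y))) >= robs - 1e-12) hits <- hits + 1L
  }
  hits / n_perm
}
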