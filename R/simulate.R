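#' Default physicochemical/microbial index anchors
#'
#' Anchor values for the nine soil indexes at the two ends of the pH
#' gradient (most acidified plantation vs. least). Group means for the
#' intermediate plantation are linearly interpolated along the pH anchors.
#' All indexes increase with pH except the fungal count, which decreases.
#'
#' @return A data frame with columns `index`, `low`, `high` and `unit`.
#' @export
default_index_anchors <- function() {
  data.frame(
    index = c("ph", "organic_matter", "cec", "mbc", "mbn",
              "respiration", "bacteria", "actinomyces", "fungi"),
    low  = c(3.29,  8.32,  7.26, 131.25, 42.37,  7.16,  7.65, 2.65, 7.43),
    high = c(5.32, 17.96, 22.48, 218.52, 78.49, 18.25, 15.42, 7.52, 2.48),
    unit = c("pH", "g/kg", "mmol/kg", "mg/kg", "mg/kg",
             "mg CO2/kg.h", "1e9 cells/g", "1e9 cells/g", "1e9 cells/g"),
    stringsAsFactors = FALSE
  )
}

#' Default two-level compound taxonomy (11 superclasses / 60 classes)
#'
#' A closed vocabulary pairing each secondary "class" label with its
#' primary "superclass", sized to the two-level chemical taxonomy commonly
#' reported for soil metabolomes (ClassyFire-style naming).
#'
#' @return A data frame with columns `superclass` and `class`.
#' @export
default_taxonomy <- function() {
  voc <- list(
    "Benzenoids" = c(
      "Naphthalenes", "Benzene and substituted derivatives", "Phenols",
      "Anthracenes", "Indanes"),
    "Hydrocarbons" = c("Alkanes", "Alkenes", "Alkynes", "Cycloalkanes"),
    "Organic acids and derivatives" = c(
      "Carboxylic acids and derivatives", "Hydroxy acids and derivatives",
      "Keto acids and derivatives", "Organic sulfonic acids and derivatives",
      "Peptidomimetics", "Vinylogous acids"),
    "Organic nitrogen compounds" = c(
      "Organonitrogen compounds", "Amines", "Quaternary ammonium salts"),
    "Organoheterocyclic compounds" = c(
      "Azoles", "Diazines", "Piperidines", "Azolidines", "Benzothiazoles",
      "Diazinanes", "Imidazopyrimidines", "Lactams",
      "Pyridines and derivatives", "Quinolines and derivatives", "Furans",
      "Indoles and derivatives", "Oxanes", "Pyrans", "Tetrahydrofurans"),
    "Organosulfur compounds" = c("Thioethers", "Sulfoxides"),
    "Nucleosides, nucleotides, and analogues" = c(
      "Purine nucleotides", "Pyrimidine nucleotides", "Purine nucleosides",
      "Pyrimidine nucleosides"),
    "Lipids and lipid-like molecules" = c(
      "Fatty acyls", "Prenol lipids", "Steroids and steroid derivatives",
      "Glycerolipids", "Glycerophospholipids", "Sphingolipids",
      "Sterol lipids"),
    "Organic oxygen compounds" = c(
      "Organooxygen compounds", "Carbonyl compounds",
      "Alcohols and polyols", "Ethers"),
    "Phenylpropanoids and polyketides" = c(
      "Flavonoids", "Coumarins and derivatives",
      "Cinnamic acids and derivatives", "Isoflavonoids", "Stilbenes"),
    "Organohalogen compounds" = c(
      "Aryl halides", "Alkyl halides", "Organochlorides",
      "Organofluorides", "Halohydrins")
  )
  data.frame(
    superclass = rep(names(voc), lengths(voc)),
    class = unlist(voc, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration for the pH-gradient study design
#'
#' Bundles and validates every parameter of the synthetic-data generator:
#' the design (groups x replicates), the planted signed associations, the
#' intensity model and the missingness mechanism. Defaults emulate the
#' study conditions: 3 pH groups x 3 replicates, ~2400 features, 55
#' positively and 166 negatively pH-associated metabolites, log-normal
#' peak areas with 5% missing cells.
#'
#' @param seed Integer master seed. Per-table substreams are derived as
#'   `seed + 1` (index table) and `seed + 2` (metabolome).
#' @param n_groups Number of ordered pH groups (P1 < P2 < ...).
#' @param n_reps Replicates per group.
#' @param n_metabolites Total number of metabolite features.
#' @param n_pos,n_neg Number of planted positively / negatively
#'   pH-associated features; the rest are null.
#' @param missing_rate Expected fraction of missing cells in `[0, 1]`.
#' @param missing_mode `"mcar"` (completely at random, default) or
#'   `"censor"` (the lowest-intensity cells are censored).
#' @param effect_size Planted slope of the log-intensity mean per pH unit.
#' @param noise_sd Replicate noise sd on the log-intensity scale.
#' @param ph_anchors Strictly increasing group pH values, length `n_groups`.
#' @param index_anchors Data frame as [default_index_anchors()].
#' @param index_noise_frac Replicate sd of each index as a fraction of its
#'   anchor range.
#' @param taxonomy Data frame as [default_taxonomy()].
#' @param baseline_meanlog,baseline_sdlog Feature baseline log-intensity
#'   distribution (log-normal across features).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_groups = 3L,
                       n_reps = 3L,
                       n_metabolites = 2400L,
                       n_pos = 55L,
                       n_neg = 166L,
                       missing_rate = 0.05,
                       missing_mode = c("mcar", "censor"),
                       effect_size = 1,
                       noise_sd = 0.25,
                       ph_anchors = c(3.29, 4.74, 5.32),
                       index_anchors = default_index_anchors(),
                       index_noise_frac = 0.02,
                       taxonomy = default_taxonomy(),
                       baseline_meanlog = log(1e6),
                       baseline_sdlog = 1.5) {
  missing_mode <- match.arg(missing_mode)
  cfg <- list(
    seed = as.integer(seed), n_groups = as.integer(n_groups),
    n_reps = as.integer(n_reps), n_metabolites = as.integer(n_metabolites),
    n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
    missing_rate = missing_rate, missing_mode = missing_mode,
    effect_size = effect_size, noise_sd = noise_sd,
    ph_anchors = ph_anchors, index_anchors = index_anchors,
    index_noise_frac = index_noise_frac, taxonomy = taxonomy,
    baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog
  )
  if (length(ph_anchors) != cfg$n_groups || any(diff(ph_anchors) <= 0)) {
    stop("invalid config: `ph_anchors` must be strictly increasing with one value per group",
         call. = FALSE)
  }
  if (cfg$n_pos + cfg$n_neg > cfg$n_metabolites) {
    stop("invalid config: n_pos + n_neg exceeds n_metabolites", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate > 1) {
    stop("invalid config: missing_rate must be in [0, 1]", call. = FALSE)
  }
  if (cfg$n_groups < 2L || cfg$n_reps < 1L) {
    stop("invalid config: need at least 2 groups and 1 replicate", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

group_labels <- function(cfg) paste0("P", seq_len(cfg$n_groups))

#' Sample metadata for a configured design
#'
#' @param cfg A [sim_config()].
#' @return Data frame with `sample_id`, `group_id` (ordered factor) and
#'   `replicate`; one row per sample in group-major order.
#' @export
sample_metadata <- function(cfg) {
  grp <- group_labels(cfg)
  data.frame(
    sample_id = paste0(rep(grp, each = cfg$n_reps), "_", seq_len(cfg$n_reps)),
    group_id = factor(rep(grp, each = cfg$n_reps), levels = grp, ordered = TRUE),
    replicate = rep(seq_len(cfg$n_reps), cfg$n_groups),
    stringsAsFactors = FALSE
  )
}

#' Simulate the per-sample physicochemical and microbial index table
#'
#' Group means interpolate the anchor values linearly along the group pH
#' (monotone increasing for every index except fungi, which decreases);
#' Gaussian replicate noise is added with sd `index_noise_frac` times each
#' index's anchor range. The same config (including seed) reproduces the
#' table exactly.
#'
#' @param cfg A [sim_config()].
#' @return Data frame: sample metadata columns followed by the nine index
#'   columns in the order of [default_index_anchors()].
#' @export
simulate_index_table <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  meta <- sample_metadata(cfg)
  ph <- cfg$ph_anchors
  frac <- (ph - ph[1]) / (ph[length(ph)] - ph[1])
  anch <- cfg$index_anchors
  out <- meta
  for (k in seq_len(nrow(anch))) {
    means <- anch$low[k] + frac * (anch$high[k] - anch$low[k])
    sd_k <- cfg$index_noise_frac * abs(anch$high[k] - anch$low[k])
    vals <- rep(means, each = cfg$n_reps)
    if (sd_k > 0) vals <- vals + stats::rnorm(length(vals), 0, sd_k)
    out[[anch$index[k]]] <- pmax(vals, 0)
  }
  out
}

#' Simulate a metabolite intensity matrix with planted pH associations
#'
#' Feature baselines are log-normal (heavy-tailed peak areas). Planted
#' features add a linear-in-pH effect of `effect_size` log-units per pH
#' unit (positive or negative sign); null features have no pH dependence.
#' Replicate noise is Gaussian on the log scale. Missing cells are
#' inserted completely at random at `missing_rate`, or by low-intensity
#' censoring when `missing_mode = "censor"`. Each feature gets one
#' superclass/class annotation drawn uniformly from the taxonomy.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `matrix` (features x samples, `NA` =
#'   missing), `annotations` (metabolite_id, name, superclass, class),
#'   `truth` (list: `planted_positive`, `planted_negative`, `null_set`)
#'   and `samples` (the metadata of [sample_metadata()]).
#' @export
simulate_metabolome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  meta <- sample_metadata(cfg)
  n <- cfg$n_metabolites
  ids <- sprintf("met_%0*d", max(4L, nchar(n)), seq_len(n))

  planted <- if (cfg$n_pos + cfg$n_neg > 0) {
    sample(ids, cfg$n_pos + cfg$n_neg)
  } else character(0)
  pos_ids <- planted[seq_len(cfg$n_pos)]
  neg_ids <- setdiff(planted, pos_ids)
  sgn <- numeric(n)
  names(sgn) <- ids
  sgn[pos_ids] <- 1
  sgn[neg_ids] <- -1

  ph_sample <- rep(cfg$ph_anchors, each = cfg$n_reps)
  ph_c <- ph_sample - mean(cfg$ph_anchors)
  mu <- stats::rnorm(n, cfg$baseline_meanlog, cfg$baseline_sdlog)

  loglevel <- outer(mu, rep(1, nrow(meta))) +
    outer(sgn * cfg$effect_size, ph_c)
  if (cfg$noise_sd > 0) {
    loglevel <- loglevel + matrix(stats::rnorm(length(loglevel), 0, cfg$noise_sd),
                                  nrow = n)
  }
  m <- exp(loglevel)
  dimnames(m) <- list(ids, meta$sample_id)

  if (cfg$missing_rate > 0 && length(m) > 0) {
    if (cfg$missing_mode == "mcar") {
      m[stats::runif(length(m)) < cfg$missing_rate] <- NA
    } else {
      m[m < stats::quantile(m, cfg$missing_rate)] <- NA
    }
  }

  tax <- cfg$taxonomy
  pick <- sample.int(nrow(tax), n, replace = TRUE)
  ann <- data.frame(
    metabolite_id = ids,
    name = paste0("Compound ", sub("^met_0*", "", ids)),
    superclass = tax$superclass[pick],
    class = tax$class[pick],
    stringsAsFactors = FALSE
  )

  list(
    matrix = m,
    annotations = ann,
    truth = list(planted_positive = pos_ids,
                 planted_negative = neg_ids,
                 null_set = setdiff(ids, planted)),
    samples = meta
  )
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper producing the index table and metabolome from one
#' config, in the shape consumed by [run_pipeline()] and [write_dataset()].
#'
#' @param cfg A [sim_config()].
#' @return List: `samples`, `indexes`, `matrix`, `annotations`, `truth`.
#' @export
simulate_dataset <- function(cfg) {
  met <- simulate_metabolome(cfg)
  list(
    samples = met$samples,
    indexes = simulate_index_table(cfg),
    matrix = met$matrix,
    annotations = met$annotations,
    truth = met$truth
  )
}
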