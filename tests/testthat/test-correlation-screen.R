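test_that("a metabolite tracking an index exactly correlates at r = +/-1", {
  ds <- planted_dataset(seed = 2, n_pos = 2, n_neg = 2, n_null = 6,
                        noise_sd = 0.2)
  m <- ds$matrix
  m["met_0001", ] <- ds$indexes$ph[match(colnames(m), ds$indexes$sample_id)]
  m["met_0002", ] <- -m["met_0001", ]
  recs <- correlate_all(ds$indexes, m)
  r1 <- recs[recs$index == "ph" & recs$metabolite_id == "met_0001", ]
  expect_equal(r1$r, 1)
  expect_lt(r1$p, 0.05)
  expect_equal(r1$n, 9L)
  r2 <- recs[recs$index == "ph" & recs$metabolite_id == "met_0002", ]
  expect_equal(r2$r, -1)
  expect_identical(r2$sign, "-")
  # deterministic ordering: index then metabolite id
  expect_equal(recs, recs[order(recs$index, recs$metabolite_id), ],
               ignore_attr = TRUE)
})

test_that("constant or sparse metabolites are skipped with a reason", {
  ds <- planted_dataset(seed = 2, n_pos = 2, n_neg = 2, n_null = 6,
                        noise_sd = 0.2)
  m <- ds$matrix
  m["met_0003", ] <- 5
  m["met_0004", c(3:9)] <- NA
  recs <- correlate_all(ds$indexes, m)
  sk <- attr(recs, "skipped")
  expect_setequal(sk$metabolite_id, c("met_0003", "met_0004"))
  expect_false(any(recs$metabolite_id %in% sk$metabolite_id))
  expect_match(sk$reason[sk$metabolite_id == "met_0003"], "constant")
  expect_match(sk$reason[sk$metabolite_id == "met_0004"], "fewer")
})

test_that("sample-id mismatch between tables is an alignment error", {
  ds <- planted_dataset(seed = 2, n_pos = 1, n_neg = 1, n_null = 2)
  idx <- ds$indexes
  idx$sample_id[1] <- "bogus"
  expect_error(correlate_all(idx, ds$matrix), "alignment")
})

test_that("null p-values are uniform (Kolmogorov-Smirnov)", {
  cfg <- sim_config(seed = 31, n_metabolites = 10000, n_pos = 0, n_neg = 0,
                    missing_rate = 0)
  ds <- simulate_dataset(cfg)
  # on the log scale the intensity model is Gaussian, so the t-based
  # null p-values are exactly uniform; raw-scale peak areas are
  # heavy-tailed and only approximately calibrated mid-distribution.
  # KS needs iid draws, so test against a single index: p-values of one
  # metabolite against the nine collinear indexes are dependent.
  recs <- correlate_all(ds$indexes, log(ds$matrix))
  p_ph <- recs$p[recs$index == "ph"]
  expect_gte(length(p_ph), 10000)
  # any genuine miscalibration at this sample size drives the KS p to
  # ~0; a 5%-level assertion would instead fail for 1 in 20 seeds
  ks <- suppressWarnings(stats::ks.test(p_ph, "punif"))
  expect_gt(ks$p.value, 1e-4)
  # absolute calibration: rejection rate at 0.05 within one percentage
  # point and mean p near 0.5 (catches wrong df, one-sided p, etc.)
  expect_lt(abs(mean(p_ph < 0.05) - 0.05), 0.01)
  expect_lt(abs(mean(p_ph) - 0.5), 0.01)
})

test_that("planted 55/166 features are recovered with the exact sign split", {
  ds <- planted_dataset(seed = 7)  # 55 pos + 166 neg, no nulls, sd 0.001
  recs <- correlate_all(ds$indexes, ds$matrix)
  part <- partition_significant(recs)
  expect_length(part$positive_set, 55)
  expect_length(part$negative_set, 166)
  expect_length(part$conflicted_set, 0)
  expect_setequal(part$positive_set, ds$truth$planted_positive)
  expect_setequal(part$negative_set, ds$truth$planted_negative)
  # partition counts cover every metabolite significant for >= 1 index
  n_sig <- length(unique(recs$metabolite_id[recs$significant]))
  expect_equal(length(part$positive_set) + length(part$negative_set) +
                 length(part$conflicted_set), n_sig)
})

test_that("sign against pH predicts the opposite sign against fungi on clean data", {
  ds <- planted_dataset(seed = 9, n_pos = 10, n_neg = 10, noise_sd = 1e-4)
  recs <- correlate_all(ds$indexes, ds$matrix)
  wide <- reshape(recs[recs$index %in% c("ph", "fungi"),
                       c("index", "metabolite_id", "sign")],
                  direction = "wide", idvar = "metabolite_id",
                  timevar = "index")
  expect_true(all(wide$sign.ph != wide$sign.fungi))
})

test_that("no significant records gives three empty sets", {
  recs <- data.frame(index = "ph", metabolite_id = c("a", "b"),
                     n = 9L, r = c(0.1, -0.2), p = c(0.8, 0.6),
                     p_adj = c(0.8, 0.8), significant = FALSE,
                     sign = c("+", "-"))
  part <- partition_significant(recs)
  expect_length(part$positive_set, 0)
  expect_length(part$negative_set, 0)
  expect_length(part$conflicted_set, 0)
})

test_that("disagreeing significant signs send a metabolite to the conflicted set", {
  recs <- data.frame(
    index = c("ph", "bacteria"), metabolite_id = "m1", n = 9L,
    r = c(0.9, -0.9), p = 0.01, p_adj = 0.02,
    significant = TRUE, sign = c("+", "-")
  )
  part <- partition_significant(recs)
  expect_identical(part$conflicted_set, "m1")
  # fungi runs opposite to the rest: pH(+) with fungi(-) is coherent
  recs2 <- recs
  recs2$index <- c("ph", "fungi")
  part2 <- partition_significant(recs2)
  expect_identical(part2$positive_set, "m1")
  # majority rule anchors on pH when pH is significant
  part3 <- partition_significant(recs, rule = "majority")
  expect_identical(part3$positive_set, "m1")
})

test_that("BH correction is reported alongside and can drive significance", {
  ds <- planted_dataset(seed = 13, n_pos = 5, n_neg = 5, n_null = 200,
                        noise_sd = 0.3, missing_rate = 0)
  raw <- correlate_all(ds$indexes, ds$matrix)
  bh <- correlate_all(ds$indexes, ds$matrix, correction = "bh")
  expect_equal(raw$p_adj, stats::p.adjust(raw$p, "BH"))
  expect_identical(bh$significant, bh$p_adj < 0.05)
  expect_lte(sum(bh$significant), sum(raw$significant))
})

test_that("analytic p agrees with a 10,000-shuffle permutation oracle", {
  set.seed(17)
  n <- 9
  devs <- numeric(50)
  for (i in seq_len(50)) {
    x <- rnorm(n)
    y <- rnorm(n)
    m <- matrix(exp(y), 1, n,
                dimnames = list("met_0001", paste0("s", 1:n)))
    idx <- data.frame(sample_id = paste0("s", 1:n), ph = x)
    rec <- correlate_all(idx, log(m))
    devs[i] <- abs(rec$p[1] - perm_pvalue(x, y))
  }
  # aggregate agreement; single configurations at n = 9 can sit further
  # from the t approximation than the exact permutation p itself allows
  expect_lte(mean(devs), 0.01)
})

test_that("the bipartite network has one signed edge per significant pair", {
  ds <- planted_dataset(seed = 3, n_pos = 2, n_neg = 1, noise_sd = 1e-4)
  # restrict to two indexes so the expected edge count is exact
  idx <- ds$indexes[, c("sample_id", "group_id", "replicate", "ph", "cec")]
  recs <- correlate_all(idx, ds$matrix)
  part <- partition_significant(recs)
  net <- build_network(part, annotations = ds$annotations)
  expect_equal(nrow(net$edges), 6L)  # 2 indexes x 3 metabolites
  expect_equal(nrow(net$edges), sum(recs$significant))
  expect_true(igraph::is_bipartite(net$graph))
  sc <- igraph::V(net$graph)$superclass
  expect_true(all(is.na(sc[igraph::V(net$graph)$type_label == "index"])))

  # GraphML round-trip preserves the edge multiset
  gml <- withr::local_tempfile(fileext = ".graphml")
  sif <- withr::local_tempfile(fileext = ".sif")
  write_network(net, graphml = gml, sif = sif)
  g2 <- igraph::read_graph(gml, format = "graphml")
  e2 <- igraph::as_data_frame(g2, what = "edges")
  expect_identical(sort(paste(e2$from, e2$to, e2$sign)),
                   sort(paste(net$edges$source, net$edges$target,
                              net$edges$sign)))
  sif_df <- utils::read.delim(sif, header = FALSE,
                              col.names = c("source", "rel", "target"))
  expect_identical(sort(paste(sif_df$source, sif_df$rel, sif_df$target)),
                   sort(paste(net$edges$source,
                              ifelse(net$edges$sign == "+", "pos", "neg"),
                              net$edges$target)))
})

test_that("an empty screen yields empty but valid network files", {
  recs <- data.frame(index = character(0), metabolite_id = character(0),
                     n = integer(0), r = numeric(0), p = numeric(0),
                     p_adj = numeric(0), significant = logical(0),
                     sign = character(0))
  part <- partition_significant(recs)
  net <- build_network(part)
  expect_equal(nrow(net$edges), 0L)
  sif <- withr::local_tempfile(fileext = ".sif")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, graphml = gml, sif = sif)
  expect_true(file.exists(sif) && file.exists(gml))
  expect_equal(length(readLines(sif)), 0L)
})
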