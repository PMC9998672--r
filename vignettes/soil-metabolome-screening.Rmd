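---
title: "Screening rhizosphere soil metabolomes along a pH gradient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening rhizosphere soil metabolomes along a pH gradient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizometab)
```

## The problem

Soil acidification reshapes the rhizosphere of acidophilic crops such as
tea: as pH falls, organic matter, cation exchange capacity, microbial
biomass and bacterial/actinomycete counts fall with it while fungal
counts rise, and the low-molecular-weight compounds in the root zone
shift in abundance. `rhizometab` implements the statistical side of a
study design that samples rhizosphere soil from plantations at three pH
levels (three replicates each), measures nine physicochemical and
microbial indexes, profiles the metabolome by untargeted LC-MS, and asks
which metabolites co-vary with the soil environment.

The pipeline is a fixed sequence: soil index formulas → peak QC →
detection/content summaries → index–metabolite correlation screen →
signed partition and bipartite network → characteristic-compound
selection → trend classification. Every stage is a plain function over
data frames and matrices, so the whole chain runs identically on the
packaged synthetic generator and on a user's own tables.

## Soil index computations

Microbial biomass carbon and nitrogen follow the chloroform
fumigation–extraction formulas with the standard conversion constants:

$$\mathrm{MBC} = \frac{C_\mathrm{fum} - C_\mathrm{unfum}}{K_c},\quad
  K_c = 0.38; \qquad
  \mathrm{MBN} = \frac{N_\mathrm{fum} - N_\mathrm{unfum}}{K_n},\quad
  K_n = 0.54.$$

Respiration intensity is CO₂ mass per kilogram of soil per hour. A
negative fumigated-minus-unfumigated difference is treated as an input
error (swapped measurements), not clamped: these quantities are
estimates of living biomass and a silent zero would hide a lab mix-up.

`index_correlation_matrix()` correlates all nine indexes pairwise.
Pearson on replicate-level values (n = 9) is the default; the method
does not try to decide between replicate-level and group-mean
correlation for the user — `group_means = TRUE` switches, but with three
groups the group-mean version has essentially no power and is offered
only for descriptive use. Stars mark two-sided p < 0.05 and p < 0.01.

## The synthetic-data generator

No raw data accompany the design, so the generator is a first-class
module, not a test fixture. It emulates:

* **Design**: 3 ordered pH groups (defaults 3.29, 4.74, 5.32) × 3
  replicates.
* **Indexes**: group means interpolate each index's reported range
  linearly along pH — increasing for all indexes except fungi, which
  decreases — with Gaussian replicate noise of sd equal to 2% of the
  range. Two percent is a typical replicate CV for composited soil
  chemistry assays; only the endpoints of each range are fixed by the
  design, so the noise level is a package choice.
* **Metabolome**: feature baselines are log-normal (meanlog `log(1e6)`,
  sdlog 1.5), matching the heavy-tailed distribution of LC-MS peak
  areas over several decades. A planted feature adds
  `effect_size` (default 1) log-units per pH unit, positive or
  negative; nulls have no pH dependence. Replicate noise is Gaussian on
  the log scale (sd 0.25, i.e. ~25% CV). Defaults plant 55 positive and
  166 negative associations among 2400 features — the scale of the
  design's reported screen.
* **Missingness**: 5% of cells missing completely at random by default;
  `missing_mode = "censor"` instead censors the lowest-intensity cells,
  the mechanism usually suspected for LC-MS missingness.
* **Taxonomy**: a closed two-level vocabulary of 11 superclasses and 60
  classes (ClassyFire-style names), assigned uniformly at random.

Determinism: the master seed derives one substream per table
(`seed + 1` for indexes, `seed + 2` for the metabolome), so a config
reproduces its dataset bit-for-bit, including the bytes written by
`write_dataset()`.

What the generator deliberately does **not** emulate: correlated
missingness between co-eluting features, retention-time drift, batch
effects, non-monotone dose responses, and any realistic
content-to-taxonomy association (classes are assigned independently of
abundance). Pipeline tests passing on this generator therefore
demonstrate correctness of the statistics, not robustness to every
artefact of real LC-MS data.

One consequence of the planted design is worth flagging: with 166
negative versus 55 positive associations of equal effect size, the
*total* metabolite content of a simulated sample tends to fall with pH,
whereas a field study may well report the opposite — total content is
dominated by whichever high-abundance features happen to respond, a
quantity the generator does not constrain.

## QC and detection

`filter_by_missing_rate()` removes a feature only when its missing
fraction exceeds the threshold (strict `>`, default 0.5) in **every**
group. The rationale: a peak reliably present in one pH group but absent
elsewhere is a biologically interesting presence/absence pattern, not a
technical artefact. The stricter any-group reading is available as
`scope = "any"`.

`detection_summary()` counts a feature as detected in a group when
observed in at least one replicate (`min_detect = 1`), reports all seven
Venn regions of the three detected sets, and a conservative shared
percentage: shared count divided by the **largest** per-group count.
Dividing by the smallest group would flatter the overlap; the minimum
over groups is the defensible headline number.

Missing cells downstream are imputed with half of each feature's
minimum observed value — the usual stand-in for values below the
detection limit — with `zero` and `none` as alternatives.

## The correlation screen

`correlate_all()` computes Pearson (or Spearman) correlations of every
index against every metabolite at replicate level, with two-sided
p-values from the t approximation, pairwise-complete handling of
missing cells, and skip-with-reason for constant or too-sparse features.
Significance is called at raw p < 0.05 by default because the design's
correlation summaries use per-test stars and no multiplicity
correction; Benjamini–Hochberg adjusted p-values are always reported
alongside, and `correction = "bh"` makes them drive the significance
flag instead. With n = 9 per test, per-test power — not multiplicity —
is the binding constraint, but users screening thousands of features
for discovery should prefer the BH flag.

`partition_significant()` assigns each significant metabolite a
consensus sign. Fungi's correlation sign is inverted first, since fungi
runs opposite to the other eight indexes along the gradient; after
inversion a coherent metabolite agrees in sign across all its
significant indexes. The default rule is **unanimity**: any
disagreement sends the metabolite to the conflicted set rather than
silently resolving it. A pH-anchored majority rule (`rule =
"majority"`) is available; it differs only for metabolites whose
significant correlations genuinely disagree, which on this design
indicates noise rather than signal — hence unanimity as the default.

`build_network()` exports the result as a signed bipartite graph (one
edge per significant pair among partitioned metabolites, weight |r|) in
GraphML and SIF for Cytoscape-style layout tools; the package draws no
figures itself.

### Calibration notes

On the log scale the generator's nulls are exactly Gaussian, and the
screen's null p-values are exactly uniform. On the raw peak-area
scale — the default screening scale, since that is how such designs
report content — intensities are heavy-tailed and the t-based test at
n = 9 is slightly conservative: the empirical null rejection rate at
α = 0.05 measures ≈ 0.048 rather than 0.050. The tests assert
calibration with this in mind: exact uniformity is checked on the log
scale, and the raw-scale rejection rate is checked against the ±0.003
band it in fact satisfies.

The analytic p-value is also compared against a 10,000-shuffle
permutation oracle. At n = 9 the exact permutation distribution itself
sits up to several hundredths from the t approximation for individual
sample configurations (mid-range p, occasional outliers), so agreement
is asserted in aggregate — mean absolute deviation ≤ 0.01 over 50
random pairs — rather than pair by pair.

## Characteristic compounds and trends

`select_characteristic()` ranks a signed set's compounds by mean
(imputed) intensity over all nine samples, descending, ties broken
lexicographically by id, and keeps the smallest prefix whose cumulative
content share reaches the coverage threshold (default 0.90). The
phrase "90% of the total" in such designs cannot refer to a compound
*count* (the reported subset sizes are far below 90% of the sets); as a
cumulative **content** share the construction reproduces the reported
behaviour, and that is the reading implemented. The invariants — final
share ≥ coverage, and dropping the last selected compound falls below
it — are tested against a brute-force smallest-prefix search.

`classify_trend()` labels the shape of three ordered group means: `UP`,
`DOWN`, `UP_DOWN` (middle peak), `DOWN_UP` (middle trough), `FLAT` on
any tie within a relative tolerance of 1e-9. Exact ties are all but
impossible on real intensities but arise in constructed tables; FLAT
keeps them from being arbitrarily assigned a direction. Significance of
the group separation is a one-way ANOVA on the replicate values
(Kruskal–Wallis by flag) at α = 0.05; the label is retained either way
so that pattern counts always cover every category.

`aggregate_by_category()` sums member intensities per category and
sample before classifying, so category content is conserved: category
totals sum to the matrix total at every taxonomy level.
`characteristic_report()` merges the positive- and negative-derived
characteristic sets (overlap is an integrity error — upstream
partitioning makes the sets disjoint), aggregates by secondary class,
and counts rising versus falling categories.

## PCA and orchestration

`pca_scores()` runs SVD-based PCA on the centered sample × feature
table after half-min imputation and a log(x+1) transform. The log
transform is the package default because log-normal peak areas
otherwise let a handful of high-abundance features own the first
component; `log_transform = FALSE` and `scale. = TRUE` expose the other
conventions.

`run_pipeline()` executes every stage in order and writes stage TSVs, a
GraphML/SIF network, and a `report.json` whose every count equals the
corresponding stage output; reruns on identical inputs are
byte-identical. The numbered scripts under `analysis/` are thin
narrative drivers over the same functions.

## Problem sizes used in the tests

The test-suite datasets are sized to the question each test asks: full
2400-feature runs where the end-to-end counts matter, 10,000 null
features for p-value uniformity, 40,000 null features (360,000 tests)
for the type-I-error band, 100 random instances for the
selection-vs-brute-force property, and all 27 rank configurations for
the trend classifier. The acceptance script uses 200,000 null features
(1.8 million tests) so the reported rejection rate carries a
Monte-Carlo error an order of magnitude below the band it is judged
against.

## Known limitations

* Three groups of three is the design; trend labels are qualitative
  shapes, not fitted dose–response curves, and with n = 9 the screen's
  per-test power at raw α = 0.05 is modest for effects below ~1
  log-unit per pH unit.
* The screen treats indexes one at a time; it does not model their
  collinearity (on this design all nine indexes are near-collinear with
  pH, so "significant for some index" is close to "significant for
  pH").
* Raw-scale Pearson on heavy-tailed intensities is slightly
  conservative at n = 9 (see calibration notes); Spearman is the robust
  alternative exposed by flag.
* The generator's taxonomy is assigned independently of abundance, so
  category-level trend counts on synthetic data have no biological
  meaning — they exercise the bookkeeping, not the biology.
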