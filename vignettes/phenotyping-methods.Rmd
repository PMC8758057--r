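---
title: "Methods: unsupervised phenotyping of perceived bladder pain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unsupervised phenotyping of perceived bladder pain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bladderphen)
```

## The problem and the data model

Interstitial cystitis / bladder pain syndrome (IC/BPS) is diagnosed by
exclusion and almost certainly pools several distinct pathologies that
present with overlapping symptoms. This package implements an
unsupervised phenotyping pipeline over patient-reported outcome
questionnaires: subjects answer a battery of four validated instruments
(O'Leary-Sant ICSI/ICPI, OAB-q short form, female Genitourinary Pain
Index, PFDI-20; 49 items total, `battery_items()`), the item-level
answers are clustered to discover symptomatic phenotypes, and the
phenotypes are profiled, stress-tested for stability, and related to
treatment response.

Three symptomatic phenotypes organise the whole package:

* **BPS** — bladder-specific pain tied to the filling/voiding cycle;
* **NUPP** — non-urologic pelvic pain centred on urethra/vagina,
  unrelated to voiding;
* **MFP** — myofascial pelvic pain with pressure, incomplete-emptying
  and defecatory symptoms.

## Scoring rules

Subscales are raw item sums except the PFDI-20, whose three subscales
(POPDI-6, CRADI-8, UDI-6) are 25 × the mean of their items (each 0–100,
total 0–300). The OAB-q symptom scale is deliberately scored as the raw
sum of items 2–6 and 8, not the instrument's official 0–100 transform,
so that scored totals are directly comparable with per-item group means.
Missing answers are an error: silent imputation of symptom items changes
phenotype assignment, so completeness is enforced at the I/O boundary
(`read_cohort_csv()`).

Two screening composites are config-driven (`composite_config()`)
because their constituent item sets come from prior work and are not
fixed here: the bladder pain composite index (BPCI; case if score > 4,
control if < 3, indeterminate between) ships with a documented stand-in
item set {icsi_4, icpi_4, fgupi_2c, fgupi_2d} at unit weights, and the
urge incontinence composite index (UICI) with {oabq_4, oabq_8, pfdi_16}.
Replace these defaults with the published definitions where available.

Three per-subject severity measures summarise the phenotype domains
(`compute_phenotype_measures()`): the bladder-pain measure is an
equal-weight mean of cohort z-scores of {icsi_4, fgupi_2c, fgupi_6}
(weights exposed; the source analysis says only "weighted composite");
the non-urologic pelvic pain measure counts endorsed pain
locations/activities (0–5); the myofascial measure averages unit
(min–max) scaled scores of {fgupi_5, pfdi_05, pfdi_01, pfdi_07}. Unit
scaling keeps the myofascial measure in a fixed [0, 1] range, which is
what the SOM pie glyphs and bin-purity rules need.

## The synthetic cohort generator

No patient-level data are distributed with the analysis this package
re-implements, so `generate_cohort()` emulates the study conditions:
145 symptomatic cases in three phenotype groups of 56 (BPS), 31 (NUPP)
and 58 (MFP) plus 69 asymptomatic controls (`phenotype_group_sizes()`;
the group-size-to-phenotype mapping is inferred from the follow-up
counts of the treatment table). Each group's per-item means and SDs —
and endorsement proportions for the eight binary pain items — are the
published per-group item statistics, encoded in
`phenotype_profiles()`.

Ordinal items are drawn from a **discretized, range-truncated normal**:
probability mass proportional to the normal density at each integer
scale point, location found by bisection so the mean matches its target
within 0.01, scale chosen to bring the SD as close as the discrete
support allows (`moment_match_item()`). Some printed SDs are not
realisable on the support (e.g. a mean of 0.07 with SD 1.03 on a 0–4
item); the generator then takes the closest achievable SD rather than
distorting the mean. Binomial-thinning families were rejected because
they cannot match the printed SDs as flexibly. Binary items are
Bernoulli with the printed endorsement proportion.

Controls have no published item table; the package uses a single fixed
asymptomatic profile chosen once: ordinal means 0.3 above the scale
floor with SD 0.6, binary endorsement 0.05, pain VAS mean 0.5. These
values put control BPCI scores well below the screening threshold while
retaining a little response noise, as asymptomatic clinic populations
show.

Items are independent within subject by default, because the published
tables carry no covariance information. Real questionnaire items are
positively correlated, so a one-parameter extension is provided: a
shared latent severity factor per subject coupled to every item through
a Gaussian copula (`correlation` in `cohort_config()`, default 0).
Mixed-phenotype subjects — emulating the observed intermediate symptom
bins — are drawn from convex blends of two groups' parameter vectors
(`mixed_fraction`, default 0; blend weight 0.5).

**What passing tests do and do not show.** Generator-based tests verify
that the pipeline recovers structure that is really there under the
published group statistics; they cannot certify behaviour under the
item correlations, floor effects and reporting idiosyncrasies of real
patients. In particular, item independence makes the synthetic groups
*easier* to separate than real ones (label-recovery kappa ≈ 0.99 here
versus bootstrap Jaccard ≈ 0.5–0.7 reported on real data).

## Two-step clustering

Features are the 49 individual items (not subscale totals): binary
items pass through as 0/1, ordinal items are z-scored, with optional
log1p pre-transforms (default none, since no item list for "log
transformed where indicated" was published). Controls are excluded from
cluster derivation.

Step one, `ward_dendrogram()`, runs Ward's minimum-variance
agglomeration with merge heights equal to the increase in total
within-cluster sum of squares (so singletons merge at half their
squared Euclidean distance); it is implemented through
`stats::hclust(method = "ward.D")` on squared-distance/2
dissimilarities, which propagates exactly those merge costs. Step two,
`kmeans_fit()`, is Lloyd's algorithm from k-means++ starts, best of 50
restarts by WSS, tolerance 1e-6 on centroid movement, at most 300
iterations; assignment ties go to the lowest cluster index and an
emptied cluster is re-seeded at the point farthest from its centroid.
`stats::kmeans` is kept as an independent cross-check in the tests, not
as the implementation, because it offers neither k-means++ seeding nor
these tie-break rules.

**Choosing k.** `suggest_k()` automates the elbow as the k with the
largest second forward difference of the WSS curve. On the default
synthetic cohort this rule sits on a near-tie between k = 2 and k = 3:
with independent items, the within-group variance of the two urinary
phenotypes overlaps enough that the second elbow is shallow, and across
generator seeds the rule picks 2 more often than 3 — even though
K-means at k = 3 recovers the three generating groups almost perfectly
(kappa ≈ 0.99). The pipeline therefore pins k = 3, the study design,
by default (`pipeline_config(k = 3)`), while still reporting the full
WSS scan and the automated suggestion; set `k = NULL` to follow the
elbow instead.

Ordination for display uses Bray–Curtis dissimilarity on unit-scaled
raw scores — not z-scores, which would violate Bray–Curtis'
non-negativity requirement — followed by classical MDS
(`pcoa_bray()`). A pair of all-zero profiles is defined to have
dissimilarity 0.

## Bootstrap cluster stability

`bootstrap_stability()` resamples subjects with replacement, refits
K-means at the reference k, aligns the replicate's arbitrary cluster
numbering to the reference by the permutation maximising unweighted
Cohen's kappa (`align_labels()`; exhaustive over k! permutations), and
computes two per-cluster indices over the unique resampled subjects:

* **Rand** (as used here): the fraction of common subjects whose in/out
  membership for the cluster agrees — joint absence counts, so a small
  cluster can score high on absences alone;
* **Jaccard**: intersection over union of memberships (1 when both
  empty); > 0.7 is the conventional "very good agreement" bar.

Point estimates are replicate means with 2.5/97.5 percentile intervals.
Subjects absent from a resample are excluded from that replicate's
agreement computation (their bootstrap assignment is undefined without
an extra rule); an optional `out_of_sample = "nearest"` mode assigns
them to the nearest replicate centroid for sensitivity analysis. The
source analysis reports both 10,000 replications and a resample of 500;
this package defaults to B = 10,000 with resample size n (the standard
bootstrap), both configurable, and its own tests and pipeline default
use B in the hundreds-to-1,000 range — problem sizes chosen to keep the
full suite fast while leaving the estimator unchanged. Each replicate
is refit from 10 k-means++ restarts, not one: with a single fresh init
an occasional bad local optimum contaminates the index with
initialisation noise that is not cluster instability.

## Variable importance and item selection

`rf_importance()` fits a random forest (500 trees, ⌊√p⌋ features per
split — the reference defaults of the cited method) on the item matrix
against cluster labels and reports permutation importance (mean
decrease in out-of-bag accuracy) and mean decrease in Gini impurity.
`phenotype_z_matrix()` expresses each item's group mean as a z-score
against the overall cohort, and `select_discriminatory_items()` assigns
each of the top-n items (default 20) to the phenotype with its largest
z entry, ties to the earlier column and flagged. On synthetic cohorts
the binary bladder-filling item is reliably the BPS column's maximum —
the direct consequence of its calibrated endorsements (0.79 vs
0.58/0.25) — but it does not reliably enter the top 20 by permutation
importance, because with independent items many continuous items carry
more three-way discrimination; the tests assert the z-matrix property
and the assignment mechanism rather than a fixed rank.

## Self-organizing map

`train_som()` implements online Kohonen training on a 6 × 4 rectangular
grid (24 bins): per iteration one random subject is drawn, its
best-matching unit (BMU) found by Euclidean distance, and every node
moved toward the subject with a Gaussian neighborhood factor. Defaults
follow the source analysis (1,000,000 iterations, initial learning rate
0.1); the decay schedules are unspecified there, so both the learning
rate and the neighborhood radius decay linearly, from (0.1,
max(rows, cols)/2) to (≈0, 0.5). Codebooks initialise uniformly at
random within each feature's observed range, so training demonstrably
reduces quantization error. No SOM package is part of this package's
dependency set; the trainer is authored here with the update rule
stated above. The SOM input is the three unit-scaled phenotype
measures (`unit_scale_measures()`), matching the three pie slices of
the bin display; a full-item SOM is just `train_som()` on a different
matrix.

The **convergence index** is the equal-weight composite of embedding
accuracy (fraction of features whose codebook distribution is
indistinguishable from the data by two-sample t and variance tests at
alpha = 0.05) and topographic accuracy (fraction of subjects whose best
and second-best matching units are grid neighbors). The index formula
is a methodological choice of this package following the popsom
lineage; its absolute value is not comparable across formulations.

**Bin purity rules** (`classify_bins()`) are invented here — the source
figures show rings, not rules — with defaults stated and exposed: a bin
is *control* if all three mean measures are below 0.25, *global pain*
if all exceed 0.6, *pure-X* if measure X is at least twice each other
measure and at least 0.25, otherwise *mixed*. Metaclustering of nodes
(`metacluster_nodes()`) is Ward clustering of codebook vectors cut at a
user-defined count.

## Treatment responder analysis

`responder_table()` aggregates per-subject therapy attempts into
(responders, attempted) cells per phenotype × therapy with a totals
row; `responder_proportions()` reports within-group (responders /
attempted) and within-cohort (share of all responders to the therapy)
proportions, with zero-denominator cells flagged NA rather than 0.
Proportions are compared with a pooled two-sample z-test without
continuity correction (switchable), and thin wrappers expose
Mann-Whitney, chi-square and Fisher tests for group comparisons. No
multiple-testing correction is applied by default, mirroring the source
analysis; a Holm option exists in `p.adjust` form downstream of the
returned p-values.

## Numerical choices and degenerate inputs

* Moment matching tolerates |mean error| ≤ 0.01 and fails loudly
  otherwise; the SD search scans a log-spaced grid of scale parameters
  and refines locally, because extreme locations underflow the normal
  density and make naive bisection unreliable.
* Zero-variance features abort standardization with the offending
  column named; a zero SD in the z-scored bladder-pain measure is a
  degenerate-feature error.
* K-means empty clusters re-seed at the farthest point; Lloyd never
  increases WSS, which the tests assert.
* All stochastic stages take explicit integer seeds; the pipeline
  derives stage seeds from one global seed via `stage_seed()`
  (deterministic hash, < 2^31), and `run_pipeline()` is byte-identical
  across reruns of the same config.
* Problem sizes in the shipped tests (bootstrap B ≤ 1,000, SOM ≤ 1e5
  iterations, forests ≤ 500 trees) are the package's own desk-scale
  choices; all defaults scale up by configuration.

## Known limitations

* The generator reproduces first and second moments per item and group,
  not inter-item covariance (beyond the optional single-factor knob) or
  skewed/zero-inflated shapes beyond what the truncated normal family
  allows.
* BPCI/UICI default item sets are stand-ins, not the published
  definitions.
* The convergence-index formula and the bin-purity thresholds are
  package choices; compare values only within this package.
* Real-data quantities from the source study (cluster sizes, stability
  indices, the 38% pure-bin fraction) depend on non-deposited patient
  data and are qualitative references only.

## A minimal run

```{r, eval = FALSE}
res <- run_pipeline(pipeline_config(seed = 1, B = 1000,
                                    som_iterations = 1e5))
print(res)
res$summary$cluster_sizes
res$stability
head(res$importance$importance)
```
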