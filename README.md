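# bladderphen

Unsupervised phenotyping of perceived bladder pain from patient-reported
outcome questionnaires.

Interstitial cystitis / bladder pain syndrome (IC/BPS) is a diagnosis of
exclusion that pools patients whose pain plausibly has different origins
— bladder-specific pain tied to the filling/voiding cycle (BPS),
non-urologic pelvic pain centred on urethra and vagina (NUPP), and
myofascial pelvic pain with pressure and defecatory symptoms (MFP).
`bladderphen` implements, end to end, the analysis that separates these
phenotypes from questionnaire data alone, for clinical researchers
working with symptom batteries:

* **Scoring** of the four-instrument battery (O'Leary-Sant ICSI/ICPI,
  OAB-q SF, female Genitourinary Pain Index, PFDI-20; 49 items), all
  subscales, the BPCI screening gate (case if > 4, control if < 3), the
  UICI, and three composite phenotype severity measures.
* **Two-step clustering**: Ward's minimum-variance dendrogram (merge
  heights = within-cluster SS increases) with elbow-method selection of
  k, then K-means (Lloyd + k-means++ starts, best of 50 restarts by the
  objective `WSS = Σᵢ ‖xᵢ − c(ℓᵢ)‖²`), plus Bray–Curtis PCoA for
  display.
* **Bootstrap cluster stability**: resample with replacement, refit,
  align replicate labels by maximal Cohen's kappa over all k!
  permutations, and report per-cluster Rand (share of subjects whose
  in/out membership agrees) and Jaccard (|A∩B|/|A∪B|) indices with
  percentile 95% CIs.
* **Variable importance**: random-forest mean decrease in accuracy and
  Gini, per-item phenotype z-score matrices, and top-item assignment to
  phenotypes.
* **Self-organizing map**: online Kohonen training on a 6 × 4
  rectangular grid with Gaussian neighborhood
  (`w ← w + α(t)·exp(−d²/2σ(t)²)·(x − w)`), convergence diagnostics,
  node metaclustering, and bin purity labels
  (control / pure phenotype / mixed / global pain).
* **Treatment responder analysis**: phenotype × therapy contingency
  tables, within-group and within-cohort proportions, pooled
  two-proportion z-tests.
* **A calibrated synthetic-cohort generator**: discretized truncated
  normal distributions moment-matched per item to published per-group
  means/SDs (binary items Bernoulli), with the study's group sizes
  (56 BPS / 31 NUPP / 58 MFP cases + 69 controls), optional mixed
  phenotypes and a latent severity correlation knob — so the whole
  pipeline is testable without patient data.

## Worked example

```r
library(bladderphen)

# score the MFP group's published mean item profile
profiles <- phenotype_profiles()
mfp <- setNames(profiles$mfp_mean, profiles$item_id)
score_pfdi(mfp)$popdi6
#> [1] 51

# full pipeline on the default synthetic cohort
res <- run_pipeline(pipeline_config(seed = 1, B = 1000,
                                    som_iterations = 1e5))
print(res)
#> Phenotyping pipeline: 214 subjects ( 145 cases, 69 controls )
#> k = 3 ; cluster sizes: 56/31/58
#> SOM convergence index: 0.951

round(res$stability$clusters[, c("rand_point", "jaccard_point")], 3)
#>   rand_point jaccard_point
#> 1          1         0.999
#> 2          1         0.999
#> 3          1         1.000

head(res$importance$importance, 3)
#>   feature mean_decrease_accuracy mean_decrease_gini
#> 1 pfdi_13               19.05604           9.364125
#> 2 pfdi_14               15.58058           6.647188
#> 3  icpi_1               13.86624           5.047227
```

The pipeline recovers the three generating phenotypes exactly
(cluster sizes 56/31/58 match the group sizes the generator planted),
with near-perfect bootstrap stability — expected under the generator's
item-independence, and a ceiling rather than a forecast for real
cohorts, where reported Jaccard values run 0.5–0.7. The top importance
items are defecatory/urgency items that split MFP from the other
groups. Per-stage tables (labels, WSS curve, stability, importance,
z-matrix, SOM bins, responder tables, `summary.json`) are written under
`out_dir` when set.

## Documentation

The methods vignette (`vignettes/phenotyping-methods.Rmd`) describes
the scoring rules, generator calibration, clustering and stability
machinery, SOM training, all tunable parameters with defaults and
rationale, and known limitations.
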