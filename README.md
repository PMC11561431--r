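# detana

Determinant analysis of behavioral intention from 5-point Likert
questionnaires.

Health-behavior studies routinely face the same analytical question: out
of dozens of questionnaire statements about a behavior (trust, perceived
ease, privacy concerns, felt responsibility, ...), **which beliefs should
an intervention target** to increase the share of people willing to
perform it? `detana` answers it with a four-stage pipeline:

1. **Descriptives** — scales harmonized so 1 is always the most favorable
   answer (reverse-coded items mapped `v → 6 − v`), incomplete
   respondents dropped and counted, per-item means/SDs and level
   proportions.
2. **Random-forest screening** — intention is dichotomized (the two most
   favorable levels = *positive*) and a random forest predicts it from
   all items; out-of-bag (OOB) permutation importance, the mean increase
   in misclassification probability (Δpmc) when a predictor's values are
   permuted, ranks the candidates. OOB pmc, sensitivity, specificity and
   AUC quantify model quality.
3. **Clustering** — the top-k determinants are grouped by average-linkage
   (UPGMA) clustering on the dissimilarity `D = 1 − |ρ|` (Spearman); the
   number of clusters minimizes *compactness − separation* (max
   within-cluster D minus min between-cluster D), and the cophenetic
   correlation reports tree fit.
4. **Change potential** — for each item and cluster, Cohen's
   `d = (mean_neu/neg − mean_pos) / SD_pooled` with 95% CI, and the
   **Potential for Change Index** `PCI = |1 − mean| · d²`: room for
   improvement times (squared) strength of association. CIBER-style plots
   visualize score distributions, group-mean CIs and d CIs.

A latent-factor generator of synthetic questionnaire data with planted
block structure and intention signal (`synthetic_design()`,
`generate_responses()`, `calibrate_effect()`) makes every stage testable
without access to panel data.

## Worked example

```r
library(detana)

design <- synthetic_design(n_respondents = 2000, n_clusters = 3,
                           items_per_cluster = c(3, 3, 2), n_noise_items = 4,
                           effect = c(2.5, 1.6, 1.0), seed = 2024)
sim       <- generate_responses(design)
responses <- harmonize_responses(sim$responses, sim$codebook)
outcome   <- dichotomize_intention(responses$intention)

fit <- fit_forest(responses, outcome, ranking_config(n_trees = 500, seed = 1))
fit
#> Random-forest intention classifier
#>   500 trees, mtry 4, 16 predictors, 2000 respondents
#>   OOB pmc 0.137 | sens 0.942 | spec 0.615 | AUC 0.920

vir <- permutation_importance(fit)
determinants <- select_determinants(vir, 8)

solution <- cluster_determinants(responses, determinants)
solution
#> Determinant cluster solution
#>   k = 3 clusters over 8 items | CCC 0.999
#>   compactness 0.371, separation 0.954
#> # A tibble: 3 × 6
#>   cluster n_items items             mean_clus sd_clus rho_clus
#>     <int>   <int> <chr>                 <dbl>   <dbl>    <dbl>
#> 1       1       3 b1_i1;b1_i2;b1_i3      2.56   0.999    0.635
#> 2       2       3 b2_i1;b2_i2;b2_i3      2.56   1.01     0.648
#> 3       3       2 b3_i1;b3_i2            2.54   1.04     0.656

tab <- change_potential_table(responses, outcome, solution$assignment)
tab[c("entity", "level", "mean", "sd", "d", "pci")]
#> # A tibble: 11 × 6
#>    entity    level    mean    sd     d   pci
#>  1 b1_i1     item     2.55 1.12  1.29  2.56
#>  2 b1_i2     item     2.56 1.15  1.24  2.40
#>  3 b1_i3     item     2.58 1.15  1.21  2.30
#>  4 cluster_1 cluster  2.56 0.999 1.49  3.46
#>  5 b2_i2     item     2.57 1.15  0.677 0.717
#>  ...
```

Reading the output: the forest separates positive from neutral/negative
intention well (AUC 0.92, "good" is conventionally ≥ 0.8); the three
planted item blocks are recovered exactly (k = 3, within-block Spearman
ρ ≈ 0.64, near-perfect tree fit CCC 0.999); and the change-potential
table orders targets by PCI — block 1, strongly associated with intention
(cluster d = 1.49) and with room for improvement (mean 2.56 on the 1–5
scale, 1 = most favorable), is the best intervention target.

`run_pipeline(pipeline_config(...))` performs all stages in one call,
writing every table (CSV with a metadata header), `metrics.json`,
`clusters.json`, figures, and a `manifest.json` with seed and content
hashes; unchanged stages are cached on rerun. `summary_report(dir)`
renders a markdown summary of a run.

## Acceptance script

`scripts/acceptance.R` recomputes, with the installed package, the
Potential-for-Change-Index values for a set of published determinant and
cluster records from their printed mean scores and effect sizes, and
writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette (`vignettes/determinant-analysis.Rmd`) documents the
models, the cluster-count rule and why it uses the signed
compactness−separation difference, the synthetic world and its
calibration, numerical edge-case policy, and known limitations.
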