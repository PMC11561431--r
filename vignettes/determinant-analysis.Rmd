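---
title: "Determinant analysis of behavioral intention: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determinant analysis of behavioral intention: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(detana)
```

## The problem

Public-health intervention development often starts from a questionnaire:
a few thousand respondents answer dozens of 5-point Likert statements
about a target behavior (here the motivating application is citizens'
willingness to perform parts of infectious-disease contact tracing
themselves with digital tools), and the analyst must decide which beliefs
— *determinants* — are worth targeting to shift the behavioral intention
of the population. `detana` implements a four-stage pipeline for that
question:

1. **Descriptives.** Scales are harmonized so that 1 is always the most
   favorable answer (reverse-coded items are mapped through
   $v \mapsto 6 - v$), incomplete respondents are dropped and counted,
   and per-item means/SDs or level proportions are reported.
2. **Screening.** A random-forest classifier predicts the dichotomized
   intention (the two most favorable answer levels count as *positive*)
   from all items, and permutation importance ranks the predictors.
3. **Grouping.** The top-ranked determinants are clustered on a Spearman
   dissimilarity with average linkage, and a compactness/separation rule
   picks the number of clusters.
4. **Prioritization.** Cohen's $d$ between the intention groups and the
   Potential for Change Index order items and clusters by how much
   leverage an intervention targeting them could have.

## Stage 2: the forest and its importance measure

The forest is a standard Breiman machine: bootstrap samples, CART trees
grown to purity with Gini splits, `mtry = floor(sqrt(p))` candidate
predictors per split (no installed R package provides the per-tree
out-of-bag bookkeeping this measure needs, so the forest lives in the
package's own Rcpp code). All performance numbers are **out-of-bag**
(OOB): each tree is evaluated on the rows its bootstrap missed, so no
separate test set is required. Reported metrics are the probability of
misclassification (pmc), sensitivity (correct-prediction probability
among positive-intention respondents), specificity, and the AUC of the
OOB positive-vote fraction. On the OOB confusion counts the identity

$$\mathrm{pmc} = \mathrm{prev}\,(1-\mathrm{sens}) +
  (1-\mathrm{prev})\,(1-\mathrm{spec})$$

holds exactly, and the test suite asserts it to $10^{-12}$.

The importance of predictor $j$ is the mean over trees of the increase in
OOB misclassification when $j$'s values are permuted among that tree's
OOB rows — an estimate of how much the model relies on $j$'s actual
values. It is reported **unscaled** (not divided by its standard error),
because the quantity of interest is an increase in pmc, in probability
units. Importance of one-hot encoded demographic levels is summed back to
the source variable. Ties in the ranking break by item id so that output
is reproducible; with fixed seeds the whole fit is bit-reproducible.

Because permutation importance splits between correlated copies of a
signal, selection uses a fixed `top_k` (default 20) rather than an
automatic cut; an auxiliary *elbow* index (position of the largest
relative drop between consecutive positive importances) is reported for
transparency but never applied automatically.

## Stage 3: Spearman dissimilarity and the cluster-count rule

Items are compared by $D_{ij} = 1 - |\rho_{ij}|$ with $\rho$ the Spearman
rank correlation (midranks for the heavy ties Likert data produces). The
absolute value makes an item and its mirror image maximally similar
($D = 0$) — deliberate, since a belief and its negation measure the same
construct. $D$ is invariant under any strictly monotone rescoring of the
items.

Average linkage (UPGMA) merges, at every step, the two clusters with the
smallest mean pairwise $D$ between their members. The implementation
recurses with the Lance–Williams update and breaks exact ties toward the
pair with lexicographically smallest member ids; tests verify it against
both a brute-force implementation that recomputes every cluster-pair mean
from the raw matrix at every step and `stats::hclust(method =
"average")`. The cophenetic correlation coefficient (CCC) — the Pearson
correlation between $D$ and the tree-implied merge heights — summarizes
how faithfully the dendrogram represents $D$; ultrametric inputs give
CCC = 1 exactly.

For every cut $k = 2, \dots, p-1$ the package reports *compactness* (the
maximum within-cluster $D$) and *separation* (the minimum between-cluster
$D$), both read from the **original** matrix rather than the cophenetic
distances — the raw dissimilarities are the observed quantity, the
cophenetic ones a model summary. The chosen $k$ minimizes the
**signed** difference $\text{compactness} - \text{separation}$, i.e.
maximizes the margin by which clusters are internally tighter than they
are mutually distant, with ties resolved toward smaller $k$ (parsimony).
The signed form matters: the absolute difference is near zero at *any*
over-split cut of clean block data (splitting a block makes the tightest
within-pair and the closest between-pair coincide), so it cannot recover
planted structure, while the signed form attains its minimum exactly at
the planted block count. The package's recovery property — planted
$K \in \{2, 3, 9\}$ recovered in at least 80% of seeded replicates at
loadings $\ge 0.8$ — is part of the acceptance suite.

Singleton clusters are legitimate outcomes (isolated determinants do
occur); their within-cluster compactness contribution is zero and their
`rho_clus` profile entry is omitted.

## Stage 4: effect sizes and the Potential for Change Index

For an item or cluster score $x$ (cluster score = the respondent's mean
over member items), Cohen's
$d = (\bar{x}_{\text{neu/neg}} - \bar{x}_{\text{pos}}) / s_{\text{pooled}}$
with the usual $(n-1)$-weighted pooled SD, so $d > 0$ whenever the
positive-intention group answers more favorably (lower). The 95% CI uses
the Hedges–Olkin normal approximation
$\mathrm{SE}(d) = \sqrt{1/n_1 + 1/n_2 + d^2 / (2(n_1+n_2))}$ — at
$n \approx 3000$ the difference from the exact noncentral-$t$ interval is
negligible. Group means get $t$-based intervals.

The Potential for Change Index is

$$\mathrm{PCI} = |1 - \text{mean}| \cdot d^2,$$

computed from the **full-sample** mean: the first factor is the room for
improvement (zero when the population already answers most favorably),
and squaring $d$ penalizes determinants weakly associated with intention.
Every emitted record satisfies this identity to machine precision, and
reported tables round to 2 decimals while machine outputs keep full
precision. Within a cluster block, item rows sort by PCI descending.

## The synthetic world

Because panel data of this kind are rarely shareable, the package ships a
generator whose defaults state a fixed, study-like world: ~3000
respondents; 9 correlated item blocks of 2–4 items (22 signal items);
38 pure-noise fillers (60 Likert items in all); one unrelated categorical
demographic; 76% positive-intention prevalence.

Each block $k$ has a latent factor $f_k \sim N(0,1)$; item latents are
$a f_k + \sqrt{1-a^2}\,\varepsilon + \mu$ with default loading $a = 0.85$
(latent within-block correlation $a^2 \approx 0.72$, Spearman $\approx
0.6$–$0.7$ after discretization) and location shift $\mu = -0.4$, which
skews responses toward the favorable end (item means near 2.3, matching
the right-skew typical of acceptability surveys). Thresholds
$(-1.2, -0.4, 0.4, 1.2)$ map the latent to the five categories. The
intention latent is $\sum_k b_k f_k + \varepsilon$ (signs arranged so
willing respondents answer favorably), dichotomized at the empirical
quantile that hits the target prevalence; the default block effects
$b_k$ range from 1.2 to 4.0, yielding item-level $d$ roughly between
0.4 and 1.0 — the magnitude range such studies report.

Where a test needs a *specific* effect size (e.g. the planted $d = 1.10$
recovery check), the required effect is obtained by `calibrate_effect()`,
which solves for $b$ on an exact large-$n$ quadrature of this latent
model rather than by trial simulation — the calibration is deterministic
and independent of the simulation seed it is later tested with.

What the generator does **not** emulate: real demographic joint
distributions, panel weighting, item-wording effects, acquiescence bias,
or missingness mechanisms (missingness is injected explicitly by tests
when needed). A green recovery test therefore establishes that the
pipeline's machinery recovers the structure this latent model plants —
not that any real questionnaire satisfies the model.

## Numerical and degenerate-input policy

* Spearman correlations are undefined for constant items: error, naming
  the item.
* `threshold_for_rate()` places the cut midway between the two order
  statistics around the target rate; an exactly tied boundary uses the
  tied value itself (closest achievable count); constant vectors error.
* Cohen's `d` errors on groups smaller than 2 or zero pooled SD rather
  than returning `Inf`.
* Average linkage can, for exotic dissimilarities, produce non-monotone
  merge heights; the package warns and keeps the sequence rather than
  silently reordering.
* All randomness (forest bootstraps, permutations, simulation, plot
  jitter) flows through R's RNG under explicit seeds; the pipeline
  derives per-stage streams from one master seed, and rerunning a
  pipeline with the same configuration reproduces every CSV byte for
  byte. Unchanged stages are skipped via content-hash caching.

## Known limitations

* Permutation importance dilutes across strongly correlated predictors —
  that is intrinsic to the measure and the reason selection is followed
  by clustering rather than taken item by item.
* The compactness/separation rule considers only the two extreme
  dissimilarities at each cut; with very unequal block tightness it can
  prefer a cut that splits the loosest block. No silhouette or
  gap-statistic alternative is offered, by design.
* Effect sizes are bivariate and unconditional: they compare marginal
  group means and deliberately say nothing about causal or conditional
  effects of intervening on a determinant.
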