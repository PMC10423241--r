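# painstrat

Data-driven biopsychosocial sub-grouping of non-specific chronic low back
pain (CLBP).

Clinical classification of CLBP has historically rested on clinician
judgment over a single domain. `painstrat` implements the alternative: an
unsupervised stratification pipeline over a participant-by-variable table
spanning nervous-system measures (quantitative sensory testing, central
sensitisation), lumbar spinal-tissue measures (quantitative MRI, trunk
strength) and psychosocial questionnaires (PROMIS short forms), for
case-control cohorts. It is aimed at pain researchers who want a
reproducible, seed-controlled reimplementation of each analytic step, plus
a synthetic-cohort generator so every stage can be exercised and tested
without access to patient data.

## The pipeline

For a table of `n` participants (cases and matched pain-free controls) by
`p` variables:

1. **Screening** — per-variable Welch two-sample t-tests case vs control at
   α = 0.05, Benjamini–Hochberg q-values (step-up:
   `q(i) = min_{j≥i} m·p(j)/j`), and removal of one member of every pair
   with |r| > 0.8 (Pearson, pairwise-complete).
2. **Feature weighting** — variables are rescaled to `[0, 1]` by their
   observed range and a 500-tree random forest of case vs control ranks
   them by out-of-bag permutation importance.
3. **Feature ranking (cases only)** — the Laplacian score on a
   k-nearest-neighbour heat-kernel graph over cases:
   `L_r = (f̃ᵣᵀ L f̃ᵣ) / (f̃ᵣᵀ D f̃ᵣ)` with `L = D − W` and `f̃` the
   degree-weighted demeaned feature; small scores mark features aligned
   with the intrinsic neighbourhood structure.
4. **Cluster validity scan** — features enter k-means in ranking order;
   Calinski–Harabasz, Davies–Bouldin and silhouette indices (evaluated on
   the full ranked-feature space) decide when adding features stops helping
   and which k is best.
5. **Fuzzy c-means** — graded memberships minimising
   `Σᵢⱼ uᵢⱼᵐ ‖xᵢ − cⱼ‖²` (m = 2), multi-restart, with within/between
   cluster distances, silhouette, and a cluster-density discrimination
   value.
6. **Classifier benchmark** — SVM (radial, one-vs-one), Gaussian naive
   Bayes, 5-NN and random forest re-identify the sub-groups over 30
   stratified 80/20 holdout splits; mean error with t-based 95% CI, with
   and without controls as an extra class.
7. **Post hoc** — one-way ANOVA + Tukey HSD of controls vs sub-groups,
   Pearson correlations (Fisher-z CIs) with pain intensity/disability,
   chi-square for categorical contrasts.

A toolkit for the derived measurement variables (multi-echo T2 by
log-linear fit, Dixon fat fraction, slice-scaled volumes,
temporal-summation and exercise-induced-hypoalgesia change scores, trial
pooling) is included, as are sub-domain analyses
(`run_subdomain()`, `combine_subdomain_labels()`) that cluster within each
biopsychosocial domain and combine the per-domain labels into an overall
participant profile.

## Worked example

The synthetic generator emulates the study design the package targets:
21 pain-free controls and 21 cases whose latent split (16 with
near-control psychosocial profiles, 5 with impaired profiles) is drawn
from the published group means and SDs.

```r
library(painstrat)
cohort <- generate_cohort(seed = 42)
fit <- clbp_pipeline(cohort$table, seed = 42)
fit
#> <painstrat pipeline>
#>   screening: 9/41 selected (3 after FDR), 9 surviving
#>   clustering: 2 features, k = 2, sizes 16/5
#>   silhouette 0.70; within 0.20/0.14; between 0.89
#>   cases-only errors: knn 0.0%, naive_bayes 0.0%, random_forest 0.0%, svm 0.0%
```

Nine of 41 variables pass screening (three survive FDR adjustment), the
validity scan settles on two psychosocial features and two clusters, and
fuzzy c-means recovers the planted 16/5 split exactly (the cases-only
benchmark re-identifies it with 0% error). The ranking that drove the
scan:

```r
head(tidy(fit$laplacian), 5)
#> # A tibble: 5 × 3
#>   variable                  score  rank
#> 1 cognitive_function        0.366     1
#> 2 general_self_efficacy     0.414     2
#> 3 social_roles_satisfaction 0.434     3
#> 4 depressive_symptoms       0.454     4
#> 5 pain_sites_12m            0.464     5
```

Adding controls back as a third class makes the task much harder, as
expected when the non-psychosocial case-control contrasts carry most of
the remaining signal:

```r
fit$benchmark_with_controls
#> <classifier benchmark> cases_plus_controls, 30 runs of 80/20 holdout
#>   knn            53.8% (49.0, 58.5)
#>   naive_bayes    42.9% (38.4, 47.5)
#>   random_forest  58.3% (52.8, 63.9)
#>   svm            40.4% (37.5, 43.3)
```

Each result type has `tidy()`/`glance()` methods and an `autoplot()`
(validity surface, sub-group profiles, benchmark errors).

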