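# neurodyad

Dyad-level analysis linking proximity in a real-world social network to
the similarity of people's neural responses while they watch the same
naturalistic stimuli.

For every unordered pair of subjects (a *dyad*), the package computes
the inter-subject correlation (ISC) of ROI-mean fMRI time series for
each of 80 anatomical regions, and asks whether dyads that are close in
the friendship network — distance 1 (mutual friends), 2, 3, or 4+ steps
apart on the graph of reciprocated nominations — are more neurally
similar than distant dyads, and whether neural similarity predicts
social distance out of sample.

The statistical core is a dyad-level proportional-odds model,

    logit P(distance_ij <= k | x_ij) = tau_k − x_ij' beta,

where `x_ij` holds the volume-weighted composite of per-ROI z-scored
similarities plus demographic dissimilarity controls (gender, ethnicity,
nationality, age difference, handedness), all standardized so each
`beta` is a per-SD log-odds change. Because every subject appears in
N − 1 dyads, standard errors are made cluster-robust by **clustering
simultaneously on both members of each dyad**:

    V = V_member1 + V_member2 − V_dyad,

each term a one-way clustered sandwich. Around this sit likelihood-ratio
tests, per-ROI regressions with Benjamini–Hochberg FDR,
Kolmogorov–Smirnov and Wilcoxon category comparisons, a
topology-preserving node-relabeling permutation test, and a linear-SVM
classifier of the four distance categories under stratified
cross-validation with within-fold oversampling and label-permutation
significance. A synthetic-data generator with a tunable planted
distance → similarity effect (`trait_decay`) supplies ground-truth
inputs for every stage; see the methods vignette
(`vignettes/neurodyad-methods.Rmd`) for the model and all design
choices.

## Worked example

```r
library(neurodyad)

cfg <- synth_config(n_subjects = 20, n_cohort = 100, n_rois = 12,
                    n_timepoints = 200, seed = 42)
st <- simulate_study(cfg)

network_stats(st$nominations)
#> Network of 100 subjects
#>   density: reciprocal 0.0408, any 0.1323
#>   reciprocity: total 0.471, dyad-level 0.308
#>   diameter (reciprocal graph): 6 [disconnected: max finite]
#>   out-degree: mean 8.57 sd 2.76 median 8 range [2, 18]
#>   in-degree:  mean 8.57 sd 2.46 median 8 range [2, 17]
```

The generated cohort sits in the empirically realistic regime: ~4% of
dyads share a mutual tie, and about 31% of tied dyads are mutual.

```r
tab <- st$dyad_table   # one row per dyad: C(20, 2) = 190
m <- dyad_model(distance ~ composite + diff_gender + diff_nationality +
                  age_diff,
                tab, family = "ordered", cluster = ~ id_i + id_j)
summary(m)
#> Dyadic ordered logistic regression (n = 190 dyads)
#>                   Estimate Std. Error z value Pr(>|z|)
#> composite        -0.633948   0.211771 -2.9936 0.002757 **
#> diff_gender       0.099985   0.175071  0.5711 0.567923
#> diff_nationality -0.088879   0.173136 -0.5133 0.607707
#> age_diff          0.111757   0.106058  1.0537 0.292006
#> Thresholds: -3.303 -1.846 0.096
#> Log-likelihood: -199.171; SEs two-way cluster-robust

odds_interpretation(coef(m)[["composite"]])
#> -47
```

The negative composite coefficient is the planted effect: a dyad one SD
more neurally similar has 47% lower odds of sitting at a larger social
distance, after the demographic controls.

```r
perm <- network_permutation_test(tab$composite,
                                 st$similarity$dyads[, c("i", "j")],
                                 tab$distance, n_perm = 1000, seed = 1)
perm
#> Node-relabeling permutation test (1000 permutations, two_sided)
#>  category observed null_mean      p
#>         1   1.0085   -0.0109 0.0050
#>         2   0.1768    0.0083 0.4286
#>         3   0.1939   -0.0063 0.0390
#>         4  -0.2839    0.0040 0.0010
```

Shuffling people across network positions (topology fixed) confirms
that distance-1 dyads are far more similar, and distance-4+ dyads far
less similar, than any relabeling of the network would produce.

File-based workflows use the same machinery end to end:
`run_pipeline("config.yaml")` reads a nomination edge list, a directory
of per-subject T×R time-series CSVs, demographics and ROI volumes, and
writes the dyad table, model JSONs, the per-ROI FDR table, the confusion
matrix and a seed log.

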