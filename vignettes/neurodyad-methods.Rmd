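---
title: "Methods: dyadic analysis of social networks and neural similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dyadic analysis of social networks and neural similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurodyad)
```

## The scientific question

When two people watch the same naturalistic stimuli, the correlation
between their brain-region response time series — the inter-subject
correlation (ISC) — indexes how similarly they attend to, interpret and
react to the world. neurodyad implements a complete dyad-level analysis
asking whether people who are close in a real-world friendship network
have more similar neural responses than people who are many social steps
apart, and whether neural similarity alone can predict social distance
out of sample.

The unit of analysis is the *dyad*: an unordered pair of subjects. For a
scanned sample of $N$ subjects there are $\binom{N}{2}$ dyads; with
$N = 42$ that is 861 dyads, each carrying one similarity value per brain
region (80 regions: 34 cortical parcels and 6 subcortical structures per
hemisphere) plus a social-distance category and demographic
dissimilarity controls.

## Pipeline overview

1. **Network** (`nomination_matrix`, `build_graph`,
   `geodesic_distances`, `network_stats`): a roster-based
   who-named-whom survey becomes a directed binary matrix; an undirected
   graph keeps reciprocated ties (a mutual nomination is the stronger
   signal of friendship; an `any`-tie rule is available); social distance
   is the geodesic (shortest-path) distance on that graph, with
   distances $\ge$ 4 and unreachable pairs collapsed into a "4+"
   category.
2. **Similarity** (`dyadic_roi_correlations`, `impute_missing`,
   `normalize_per_roi`, `weighted_composite`, `build_dyad_table`):
   Pearson correlations per dyad and ROI on the concatenated series;
   missing dyad-ROI cells (either subject lacking the region) imputed
   with the ROI's mean across observed dyads; each ROI column z-scored
   across dyads; the overall similarity is the volume-weighted mean of
   the z-scores.
3. **Dyadic regression** (`dyad_model`, `twoway_cluster_vcov`,
   `lr_test`, `per_roi_regressions`, `deviation_coded_estimates`,
   `odds_interpretation`): proportional-odds and binary logistic models
   with standard errors clustered on both members of each dyad.
4. **Resampling** (`ks_group_vs_rest`, `wilcoxon_group_vs_rest`,
   `wilcoxon_pairwise`, `network_permutation_test`): distribution and
   location comparisons of each distance category against the rest, and
   a node-relabeling permutation test that shuffles people across
   network positions while freezing the topology.
5. **Classification** (`classifier_config`, `cross_validated_predict`,
   `label_permutation_test`): a linear SVM predicting the four distance
   categories from the 80-element similarity vectors under stratified
   cross-validation with within-fold oversampling and nested cost
   tuning.
6. **IO and orchestration** (`read_nominations`,
   `read_timeseries_dir`, `run_pipeline`, ...): one CSV dialect, a
   config-driven end-to-end runner, and a seed log for replay.

## The synthetic-data generator

Survey and imaging data of this kind are rarely shareable, so the
package ships a generator whose outputs exercise every stage with a
*known* planted effect.

**Network.** Each unordered pair receives an any-tie probability: the
base rate `tie_base_rate` (default 0.146, a realistic any-tie density
for a ~280-person cohort) modulated by demographic homophily — at
assortativity $a$ the rate is multiplied by $(1-a) + a\,[\text{same
gender}]$ and mildly boosted for shared ethnicity/nationality, so $a=1$
confines ties to same-gender pairs. A tied dyad is mutual with
probability $\max(r, p_{\text{any}})$ where $r$ is
`reciprocity_target` (default 0.309): in the sparse regime dyad-level
reciprocity sits at the target, while a saturated graph is fully mutual
(the only self-consistent limit).

**Time series.** Subject $i$'s response in ROI $r$ is

$$x_{ir}(t) = c_r(t) + \sum_{k=1}^{K} w_{ik} f_{kr}(t) +
  \sigma\,\varepsilon_{irt},$$

with a stimulus-locked signal $c_r$ common to everyone (SD
`common_signal_sd`, default 0.5), $K$ latent "interpretation
components" with shared time courses $f_{kr}$, and white noise. The
subject loadings on each component are multivariate normal with
correlation $\rho^{d(i,j)}$ ($\rho$ = `trait_decay`, default 0.5; $d$ =
capped geodesic distance). The implied expected ISC,

$$\mathbb{E}\,r_{ij} \approx
  \frac{c^2 + K\rho^{d(i,j)}}{c^2 + K + \sigma^2},$$

is strictly decreasing in distance when $\rho < 1$ and flat when
$\rho = 1$ (the null model used for calibration). The matrix
$[\rho^{d(i,j)}]$ need not be positive semidefinite, so it is repaired
by symmetric eigendecomposition with negative eigenvalues clipped to
zero and the diagonal rescaled to one — the standard nearest-PSD fix,
which preserves the monotone structure. Unreachable pairs enter
generation at the distance cap (default 4), mirroring the analysis's
"4+" category.

**Missingness.** Each (subject, ROI) series is knocked out i.i.d. with
probability `missing_rate` (default 0.009, chosen so the dyad-by-ROI
missing fraction $\approx 2m$ lands near the ~1.8% coverage loss typical
of whole-brain parcellations).

**Seeds.** Every stage derives its own stream from the master seed via
`split_seed(seed, label)` (a Lehmer step on a label hash), so identical
configurations are bit-reproducible and any stage can be regenerated in
isolation.

**What the generator does not emulate:** hemodynamics, autocorrelated
noise spectra, spatial structure across ROIs, degree heterogeneity and
community structure of real friendship networks, or any systematic
missingness (real coverage loss concentrates in temporal-lobe regions).
Passing tests on this generator therefore demonstrate the correctness
and calibration of the *machinery*, not empirical claims about real
cohorts.

## The dyadic ordered logit and two-way clustering

The core model is a proportional-odds regression with the
parameterization

$$\operatorname{logit} P(Y_{ij} \le k \mid x_{ij}) =
  \tau_k - x_{ij}^\top \beta,$$

so that a *negative* coefficient on neural similarity means more similar
dyads have shorter social distance. Predictors are standardized to mean
0, SD 1 by default (binary indicators are left alone), making each
$\beta$ a per-SD log-odds change; `odds_interpretation()` converts it to
the percent change in odds, $100(e^\beta - 1)$.

Estimation is maximum likelihood with an analytic gradient: thresholds
are parameterized through log-differences to stay ordered, BFGS runs
from thresholds initialized at the cumulative category frequencies and
zero slopes, and convergence requires the score norm below
$\max(10^{-3}, 10^{-8} n)$ with all parameters bounded away from the
separation regime (|estimate| < 30); violations are reported as explicit
failures, never silently returned. The observed information is computed
by central differences at the optimum and inverted for the model-based
covariance. The binary (friend vs not) model uses the standard
iteratively reweighted least squares fit; an aliased (constant)
predictor is reported with a zero coefficient and a warning.

Each subject appears in $N - 1$ dyads, so dyadic observations are far
from independent. The packaged remedy is two-way cluster-robust
covariance: with per-observation score contributions $s_{ij}$ and bread
$B$ (inverse observed information; $(X^\top X)^{-1}$ for least squares),

$$V = V_{\text{member 1}} + V_{\text{member 2}} - V_{\text{dyad}},$$

where each term is a one-way clustered sandwich over the first member,
the second member, and their intersection (the dyads themselves). The
assembled matrix can have slightly negative eigenvalues; they are
clipped to zero. No finite-sample multiplier is applied by default
(`cluster_adjust = TRUE` switches on $G/(G-1)$ per dimension). P-values
use the normal reference on $\beta/\widehat{\text{SE}}$ — the
conventional choice for this estimator — without a small-sample $t$
correction. With every observation its own cluster the estimator reduces
exactly to the heteroskedasticity-robust sandwich, and duplicating every
dyad leaves clustered (but not naive) standard errors unchanged; both
properties are tested.

Per-ROI analyses fit the same model once per region and correct the
family with Benjamini–Hochberg step-up FDR; regions that fail to
converge are recorded and excluded from the family with a warning,
never dropped silently. Deviation-coded contrasts (each category's
control-adjusted mean composite similarity against the average of the
other categories') come from a linear model with sum-to-zero contrasts,
scaled by $K/(K-1)$, with confidence intervals from the same two-way
clustered covariance.

## Nonparametric and permutation tests

Kolmogorov–Smirnov tests compare each distance category's composite
similarities against all other dyads (two-sided, asymptotic reference —
appropriate at hundreds of dyads per group; no exact small-sample mode
is provided). Wilcoxon rank-sum tests report $W$ as the rank sum of the
singled-out group; the p-value is exact (null enumeration) when
$n_1 n_2 \le 400$ with no ties, otherwise a normal approximation with
tie and continuity corrections.

The network permutation test draws, per iteration, a uniform random
bijection of subjects onto network positions — equivalently a
simultaneous row/column permutation of the dyadic similarity matrix —
and recomputes each category's mean composite similarity. Topology, and
hence the multiset of distance labels, never changes; only *who* sits
where does. The default p-value is two-sided around the null mean with
an add-one correction,
$p_k = \bigl(1 + \#\{|{\text{null}} - \bar{\text{null}}| \ge
|{\text{obs}} - \bar{\text{null}}|\}\bigr) / (B + 1)$;
one-sided variants are available since the appropriate tail can be a
judgment call for directional hypotheses.

## Out-of-sample classification

`cross_validated_predict` runs: stratified outer folds (default 8; per
category each fold's count differs from an even split by at most one,
with remainders steered to the smallest folds so totals stay balanced);
within-fold oversampling that brings every training class up to the
largest class by repeated full passes without replacement plus a final
uniform partial pass (every original example is retained; no class
exceeds the original maximum); nested tuning of the linear SVM cost
over a log-spaced grid (default $10^{-3}..10^{3}$, 7 points; ties go to
the smallest cost, and a single-point grid skips the search); and
prediction of the held-out dyads. Both the pooled accuracy over all
held-out predictions and the macro average (mean per-class recall) are
reported, since the aggregation convention genuinely matters for
imbalanced classes; the confusion matrix is row-normalized over true
categories. The multiclass scheme defaults to one-vs-rest (largest
decision value wins), with the pairwise-voting one-vs-one scheme as an
option — the choice is consequential only near ties.

Two deliberate fidelity notes. First, features enter as-is: the per-ROI
z-scoring uses all dyads, so fold-wise scaling statistics leak mildly
across the train/test boundary. This mirrors the transductive
normalization that is standard for this analysis; a within-fold
rescaling would be the stricter variant. Second, dyads sharing a subject
may appear in both training and test folds by default; the strict
`subject_disjoint` mode partitions *subjects* into folds, tests only
within-fold dyads and trains only on dyads with neither member in the
test fold (at the price of discarding spanning dyads from evaluation).

`label_permutation_test` reruns the identical pipeline with the
training labels of each fold shuffled (held-out labels keep their truth
for scoring), giving
$p = (1 + \#\{\text{null} \ge \text{obs}\}) / (B + 1)$.

## Numerical choices and degenerate inputs

- Z-scoring uses the sample SD ($D - 1$); a population-SD mode is a
  switch. Imputation happens *before* normalization, and imputed cells
  stay in downstream models (flagged).
- Zero-variance time series yield missing correlations with a warning —
  never a fabricated 0. A fully missing ROI, a zero-SD similarity
  column, an empty distance category, or a negative volume abort with a
  named error.
- Dyads are canonically ordered ($i < j$ by subject position, ids sorted
  on read), so every stage agrees on the dyad index.
- The diameter of a disconnected graph is reported as the maximum
  finite geodesic with a `connected = FALSE` flag, matching common
  network tooling.
- All Monte-Carlo machinery (generator, permutations, folds,
  oversampling) restores the caller's RNG state.

## Problem sizes used by the test suite

The package's own test suite verifies oracle equivalences (geodesics vs
Floyd–Warshall on graphs of up to 8 nodes; Pearson vs the closed form at
$10^{-12}$; exact Wilcoxon vs full enumeration for all group sizes up to
5; BH vs a brute-force step-up oracle; the two-way sandwich vs a hand
computation) and statistical calibration: ordered-logit recovery of a
planted latent slope at the design size of 861 dyads (100 replicates),
5%-level null rejection rates of the Wald, likelihood-ratio and
permutation tests inside binomial 95% bands (200 replicates each, 200
permutations per replicate at 16 nodes), classifier chance behavior on
label-shuffled data (50 replicates), and classifier power on
strong-gradient synthetic studies (`trait_decay = 0.7`,
`n_components = 16`, `noise_sd = 0.4`, 34 subjects, 150 time points;
20 replicates). These sizes were chosen to make the checks sharp while
keeping the default suite quick; the planted-gradient regime is
deliberately strong because with fast trait decay the middle distance
categories are close to indistinguishable *by construction* — a
property of the generative model, not a defect of the classifier.

## Known limitations

- The proportional-odds assumption is imposed, not tested; real dyadic
  data may violate it.
- The two-way clustered estimator is asymptotic in the number of
  clusters (subjects); with few subjects its p-values are approximate,
  and no small-sample correction is applied by default.
- The permutation test treats the composite similarity matrix as
  exchangeable under node relabeling, which holds under the null of no
  position effect but not under, e.g., subject-level scanner artifacts
  correlated with network position.
- The generator's homophily mechanism is stylized (gender-gated); it
  exists to give the controls variance, not to model real assortativity.
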