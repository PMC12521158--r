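---
title: "Graph-theoretic connectome analysis for treatment-response prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-theoretic connectome analysis for treatment-response prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(fcresponse)
library(dplyr)
```

## The analysis in one paragraph

`fcresponse` implements a complete graph-theoretical analysis of
resting-state functional brain networks for studies asking whether
pre-treatment network topology predicts antidepressant (SSRI) treatment
response. Starting from cleaned regional BOLD time series (one
timepoints-by-ROIs matrix per subject, typically the 90 cerebral regions
of the AAL parcellation), the pipeline (i) computes Pearson functional
connectivity matrices, (ii) binarizes them across a sweep of sparsity
thresholds, (iii) computes global and nodal topological metrics on every
binary graph, normalizing clustering and path length against
degree-preserving random networks, (iv) integrates each metric curve over
the sweep (AUC) to obtain threshold-insensitive summaries, (v) compares
groups (responders vs non-responders to 8 weeks of treatment, defined by
a ≥ 50% reduction of the 17-item Hamilton Depression Rating Scale) with
nonparametric permutation tests, FDR-corrected across nodes, and
(vi) relates topology to symptom change via age- and sex-adjusted partial
correlations and builds a forward likelihood-ratio logistic model of
responder status with ROC characterization. A synthetic cohort generator
with a modular block-correlation model makes every stage testable without
scan data.

## The sparsity sweep and AUC integration

A weighted connectivity matrix has no privileged edge set, and binary
topology depends strongly on the chosen density. The standard remedy,
implemented here, is to threshold the matrix at each sparsity `s` in a
grid — keeping the top `round(s * N(N-1)/2)` edges by correlation
strength — and to integrate each metric over the grid by the trapezoidal
rule. The default grid is 0.10 to 0.34 in steps of 0.01 (25 thresholds):
below ~0.10 connectome-scale graphs fragment; above ~0.34 topology
approaches that of a dense random graph. The AUC of a metric which is
constant at 1 over this grid is 0.24, which sets the scale of all
AUC-integrated quantities.

Details that matter for exact reproducibility:

* Edge counts use round-half-up, so counts are bit-reproducible across
  platforms (base R's `round()` rounds half to even).
* Ranking is by signed correlation, so strongly negative edges enter
  last, matching common connectome-toolbox behaviour; an absolute-value
  mode is available (`rank_by = "absolute"`).
* Ties at the cut are broken by ascending `(i, j)` lexicographic order —
  deterministic, no RNG.
* Because thresholding is rank-based, edge sets are nested along the
  grid, and binarization is invariant to any strictly increasing
  transform of the weights (hence applying a Fisher z-transform first
  would change nothing and is omitted).

## Graph metrics

All metrics operate on undirected binary graphs with the conventional
definitions: clustering coefficient `2t/(k(k-1))` (0 for degree < 2),
characteristic path length as the mean shortest-path distance,
efficiency as mean inverse distance, local efficiency of a node as the
global efficiency of the subgraph induced by its neighbours, betweenness
by Brandes' dependency accumulation (unnormalized pair counts — only
group contrasts matter and any fixed normalization cancels),
assortativity as the Pearson correlation of degrees across edge
endpoints, and modularity Q of the best partition found by seeded greedy
(Louvain) optimization, best of 10 restarts by default (the best-of-runs
Q is nondecreasing in the number of restarts).

Two choices deserve emphasis because the literature is not uniform:

* **Disconnected graphs.** At low sparsity a graph may fragment. `Lp` is
  averaged over *connected* ordered pairs only; efficiency-type metrics
  handle disconnection naturally via `1/∞ = 0`. This changes `lambda` on
  fragmented low-sparsity graphs relative to conventions that substitute
  N for unreachable distances.
* **Local efficiency.** The neighbour-subgraph definition is used:
  shortest paths are confined to the induced subgraph of the node's
  neighbours (the Brain Connectivity Toolbox convention). Some libraries
  allow those paths to leave the neighbourhood, which yields larger
  values; the package's tests pin the intended definition against an
  independently composed reference.

Shortest paths, betweenness, clustering, local efficiency and the null
rewiring run in C++ (the null ensembles dominate the budget: at default
settings each subject requires 2,500 rewired graphs).

## Small-world normalization

Raw `Cp` and `Lp` are confounded by degree structure, so they are
normalized by their means over `n_nulls` degree-preserving random
networks (Maslov–Sneppen double-edge swaps, 10 attempted swaps per edge,
rejecting self-loops and multi-edges): `gamma = Cp/<Cp_null>`,
`lambda = Lp/<Lp_null>`, and the small-worldness scalar
`sigma = gamma/lambda`, with `sigma > 1` indicating small-world
organization. The default ensemble size is 100 per graph, which makes the
ensemble noise in `gamma`/`lambda` small relative to the group effects
the pipeline is designed to detect; smaller ensembles (15–25) are
adequate for simulation studies where group means over ~70 subjects are
compared, and the package's own validation runs use such sizes to keep
simulated-cohort studies at tractable cost (problem sizes used by the
test suite: 69-subject cohorts, 25 thresholds, 15 nulls per graph, 10
replicate cohorts). A graph admitting no valid swap (e.g. a star)
returns copies with a warning rather than failing.

All randomness is seed-controlled: each null ensemble is drawn from a
single RNG stream seeded by the caller, and the one-call C++ ensemble
path consumes the stream identically to generating the nulls one by one,
so both routes give identical normalization under the same seed.

## The synthetic cohort generator

No patient scans ship with the package; instead `simulate_cohort()`
generates cohorts whose *group covariance differs in network
segregation*, the effect structure reported in adolescent-depression
treatment-response connectomics (non-responders more segregated: higher
normalized clustering, local efficiency, modularity, small-worldness).

The generative model is deliberately minimal: each group has a
block-structured model correlation matrix — `n_modules` equal blocks
(default 6 blocks of 15 ROIs) with correlation `within_module_r` inside
blocks and `between_module_r` between them — and each subject's time
series is `n_timepoints` independent multivariate-normal draws plus
independent channel noise. Block density directly manipulates
clustering, local efficiency and modularity, which is exactly the effect
the downstream statistics are meant to detect. The model makes no
attempt to reproduce BOLD autocorrelation, head motion, physiological
noise, spatial smoothness or inter-subject covariance heterogeneity —
so passing tests demonstrate the *statistical machinery* (calibration,
power, direction) under the planted effect, not robustness to fMRI
artifacts.

Default parameters (chosen once, as the study conditions of the
package's validation suite):

| parameter | default | rationale |
|---|---|---|
| group sizes | 37 / 32 | responder / non-responder sample sizes of the motivating study design |
| ROIs, timepoints | 90, 230 | AAL-90 parcellation, retained volumes |
| within/between r (responders) | 0.300 / 0.100 | per-threshold modularity ≈ 0.44, clustering ≈ 0.5 — the order of magnitude of published AUC-integrated values once integrated over the sweep |
| within/between r (non-responders) | 0.310 / 0.097 | plants a segregation increase of ~1 pooled SD on AUC-modularity: large enough for > 80% permutation power at n = 37/32, small enough that detection is non-trivial |
| noise SD | 0.6 | attenuates model correlations ~26%, keeping empirical FC realistically noisy at T = 230 |
| HAMD-17 pre | N(18.4, 5.5²), ≥ 8, integer | moderate depression with the > 7 inclusion threshold |
| reduction, responders | U(0.55, 1.00) | post scores ~4 points on average |
| reduction, non-responders | U(−0.20, 0.35) | includes worsening; post scores near pre |

Scale scores are integers in practice, so scores are rounded after
continuous generation. Because rounding can push a score across the 50%
boundary (e.g. a pre-score of 15 reduced by 50.5% rounds to 7, a 53%
reduction, but a pre-score of 8 reduced by 55% rounds to 4, exactly
50%), the post score is clamped to the correct side of the boundary —
`≤ floor(pre/2)` for generated responders, `> floor(pre/2)` for
non-responders — so derived labels always equal the generating group.
The clamp moves a score by at most one point and fires only in boundary
cases. Reduction ranges that straddle 0.50 are rejected outright, since
labels would contradict generation.

Age and sex are generated independently of group by default (mirroring
cohorts with no demographic differences); `confound_age_sex = TRUE`
plants group-dependent distributions for exercising covariate
adjustment. A single master seed drives everything: clinical covariates
first, then one derived seed per subject for the time series, so cohorts
are reproducible subject-by-subject.

## Group inference

Group differences in AUC metrics use a nonparametric permutation test:
pooled values are randomly re-partitioned into groups of the original
sizes; the two-tailed p-value is `(1 + #{|null| ≥ |observed|}) /
(n_perm + 1)` (add-one smoothing, standard for Monte-Carlo tests, so p
is never 0), and the critical value is the empirical 95th percentile of
the |difference| null — under a symmetric null this is the two-tailed
rule at level 0.05 (2.5% per tail of the signed null). The default is
10,000 permutations. For whole-table comparisons all tests share one set
of permuted group assignments, computed as a single matrix product —
statistically equivalent to independent draws and far faster; the
single-test function draws its own permutations.

Nodal p-values are FDR-adjusted (Benjamini–Hochberg) *within each nodal
metric family* (one family of 90 nodes per metric), matching how nodal
results are conventionally reported per metric; both raw and adjusted
values are returned since reporting conventions differ on which to
print. Global metrics are not FDR-corrected. Degree and link-weight
distributions (pooled per group; degrees extracted at the sweep midpoint
0.22 by default, configurable) are compared with two-sample
Kolmogorov–Smirnov and Mann–Whitney U tests; U uses exact enumeration
for small tie-free samples and the tie-corrected normal approximation
otherwise.

## Clinical models

Partial correlations between topology indices and symptom measures
(pre-treatment HAMD-17 and its pre-minus-post change) control for age
and sex by residualizing both variables on the covariates with an
intercept; the p-value is the t-transform of the residual correlation
with `n − 2 − k` degrees of freedom. With no covariates this is exactly
the Pearson test.

Responder prediction uses forward likelihood-ratio logistic regression:
candidates enter by smallest LR-test p-value below `entry_p` (default
0.05) and are removed when their removal LR p-value exceeds `removal_p`
(default 0.10) — the conventional stepwise defaults. The candidate pool
is passed in explicitly (typically the metrics significant in the group
comparison) to keep the inferential chain visible. Fits use IRLS with
tolerance 1e-8 and at most 100 iterations; perfect separation is
detected from group-wise fitted probabilities and reported as an error
naming the separating feature; odds-ratio confidence intervals are Wald
intervals, matching the `OR (95% CI)` reporting convention. Sex is coded
0 = male, 1 = female (affects only intercepts). The selected model and
per-predictor univariate models are both characterized by ROC curves:
every distinct score is swept as a threshold, the AUC is the trapezoidal
integral (equal to the concordant-pair probability on tie-free data),
and the reported operating point maximizes Youden's J, ties broken
toward higher specificity. If all scores are identical the AUC is 0.5 by
convention and the operating point is the all-negative corner.

## Worked example

A small cohort end to end (settings scaled down for a fast build of this
document; defaults are 90 ROIs, 25 thresholds, 100 nulls, 10,000
permutations):

```{r example}
cfg <- pipeline_config(
  cohort = cohort_spec(n_responders = 8, n_nonresponders = 8,
                       n_rois = 20, n_timepoints = 60, n_modules = 4,
                       within_module_r = c(responder = 0.30, nonresponder = 0.38),
                       between_module_r = c(responder = 0.10, nonresponder = 0.08),
                       seed = 42),
  grid = sparsity_grid(0.15, 0.30, 0.05),
  n_nulls = 10, n_runs = 3, n_perm = 500, seed = 42)
report <- run_pipeline(cfg, output_dir = tempfile("fcr_vignette_"), quiet = TRUE)
report
```

The printed table mirrors the conventional reporting layout: per metric,
group means ± SD of the AUC-integrated values and the permutation
p-value; nodal rows additionally carry FDR-adjusted p-values.

## Known limitations

* The generator's multivariate-normal model has no temporal
  autocorrelation, so effective degrees of freedom per subject are
  higher than in real BOLD at the same T; empirical correlations are
  correspondingly less noisy.
* Lp and lambda depend on the connected-pairs convention on fragmented
  graphs (documented above); comparisons with toolboxes using other
  conventions will differ at the lowest sparsities.
* Greedy modularity optimization is stochastic and Q is a lower bound on
  the optimum; the seeded best-of-runs scheme makes results reproducible
  but not provably optimal.
* The forward-LR entry test examines each candidate at `entry_p` per
  step, so with many simultaneous candidates the family-wise entry rate
  under a global null grows accordingly (~23% with five independent null
  candidates at 0.05) — inherent to stepwise selection, not a defect of
  the implementation.
* Permutation inference assumes exchangeability of subjects under the
  null; covariate-adjusted permutation schemes are out of scope.
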