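# fcresponse

Graph-theoretic analysis of resting-state functional brain networks for
antidepressant treatment-response studies.

## The problem

In adolescent major depressive disorder, roughly half of patients respond
to a first course of SSRIs (defined as a ≥ 50% reduction of the 17-item
Hamilton Depression Rating Scale, HAMD-17, after 8 weeks). A growing
literature asks whether the *pre-treatment* organization of the
functional connectome — estimated from resting-state fMRI — already
distinguishes eventual responders from non-responders, with
non-responders typically showing a more *segregated* network (higher
normalized clustering γ, local efficiency Eloc, modularity Q and
small-worldness σ). `fcresponse` packages the full analysis chain such
studies use, from cleaned regional BOLD time series to a predictive
model, for researchers who want a tested, reproducible and scriptable
implementation.

## The method

For each subject with a T × N matrix of regional time series (typically
the N = 90 cerebral regions of the AAL atlas):

1. **Connectivity** — the N × N Pearson correlation matrix
   `r_ij = corr(x_i, x_j)` (diagonal stored as 0).
2. **Sparsity sweep** — the matrix is binarized at each sparsity
   `s ∈ {0.10, 0.11, …, 0.34}` by keeping the top `round(s·N(N−1)/2)`
   edges by correlation strength (deterministic tie-breaking; nested edge
   sets across the sweep).
3. **Topological metrics** per binary graph — global: clustering
   coefficient Cp, characteristic path length Lp, global and local
   efficiency Eglob/Eloc, assortativity, modularity Q (seeded best-of-10
   Louvain), and the small-world quantities γ = Cp/⟨Cp_null⟩,
   λ = Lp/⟨Lp_null⟩, σ = γ/λ, normalized against 100 degree-preserving
   (Maslov–Sneppen) null networks; nodal: degree, clustering, nodal
   efficiency, betweenness (Brandes).
4. **AUC integration** — every metric curve is integrated over the sweep
   (trapezoid), yielding threshold-insensitive summaries (a constant
   curve of 1 integrates to 0.24).
5. **Group inference** — permutation tests on each AUC metric
   (10,000 re-partitions; two-tailed p with add-one smoothing; 95th
   percentile of the |difference| null as critical value), with
   Benjamini–Hochberg FDR across the 90 nodes within each nodal metric;
   K-S and Mann–Whitney tests compare degree and link-weight
   distributions.
6. **Clinical models** — age/sex-adjusted partial correlations between
   topology and HAMD-17 change, forward likelihood-ratio logistic
   regression (entry p < 0.05, removal p > 0.10) predicting responder
   status from the significant metrics, and ROC curves with Youden-optimal
   operating points.

A synthetic cohort generator (modular block-correlation multivariate
normal model, group sizes 37/32, clinical marginals of an adolescent MDD
cohort) makes the whole pipeline testable without scan data; see the
methods vignette (`vignettes/network-response-analysis.Rmd`) for the
model, defaults and their rationale.

## Worked example

```r
library(fcresponse)

cfg <- pipeline_config(
  cohort = cohort_spec(n_responders = 8, n_nonresponders = 8,
                       n_rois = 20, n_timepoints = 60, n_modules = 4,
                       within_module_r = c(responder = 0.30, nonresponder = 0.38),
                       between_module_r = c(responder = 0.10, nonresponder = 0.08),
                       seed = 42),
  grid = sparsity_grid(0.15, 0.30, 0.05),
  n_nulls = 10, n_runs = 3, n_perm = 500, seed = 42)
report <- run_pipeline(cfg, output_dir = "fcr_demo", quiet = TRUE)
report
```

```
== functional connectome treatment-response analysis ==
subjects: 16 (8 responder, 8 nonresponder)
seed: 42 | package 0.1.0

global metrics (9 tests; group means +/- SD, permutation p):
  Cp            0.0520 +/- 0.0095 | 0.0755 +/- 0.0075  p = 0.0020 *
  Eglob         0.0788 +/- 0.0039 | 0.0764 +/- 0.0015  p = 0.1277
  Eloc          0.0648 +/- 0.0100 | 0.0892 +/- 0.0081  p = 0.0020 *
  Lp            0.3246 +/- 0.0114 | 0.3711 +/- 0.0195  p = 0.0020 *
  assortativity -0.0142 +/- 0.0201 | -0.0020 +/- 0.0242  p = 0.2914
  gamma         0.2233 +/- 0.0546 | 0.4019 +/- 0.0718  p = 0.0020 *
  lambda        0.1549 +/- 0.0048 | 0.1735 +/- 0.0079  p = 0.0020 *
  modularity    0.0497 +/- 0.0070 | 0.0682 +/- 0.0048  p = 0.0020 *
  sigma         0.2153 +/- 0.0496 | 0.3437 +/- 0.0536  p = 0.0020 *

nodal metrics: 80 tests, 1 significant after FDR
  clustering         ROI009   t = -3.86, p = 0.0020, p_fdr = 0.0399

forward-LR logistic model: clustering:ROI009
  ROC clustering:ROI009            AUC = 0.945 (sens 0.750, spec 1.000)
  ROC joint_model                  AUC = 0.945 (sens 0.750, spec 1.000)
```

Reading the output: the synthetic non-responder group was generated with
denser correlation modules, and the pipeline recovers exactly that
signature — higher AUC-integrated clustering, local efficiency, γ,
modularity and σ in the non-responder column (the `*` marks permutation
p below 0.05; negative t-like statistics mean responder < non-responder).
One node's clustering coefficient survives nodal FDR, is selected by the
forward-LR model, and classifies responders with an ROC AUC of 0.945 at
a Youden-optimal operating point of sensitivity 0.75 / specificity 1.00.
Every intermediate table (per-subject time series, connectivity
matrices, AUC metrics, comparison tables, correlations, model, ROC
curves, JSON report) is persisted under `output_dir`.

A command-line wrapper with `simulate` and `run-all` subcommands is
installed at `inst/cli/fcresponse-cli.R`; configuration is a YAML file
mirroring `pipeline_config()` (`read_pipeline_config()`).

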