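# leidar

Identification and group comparison of recurrent phase-locking brain
states in resting-state fMRI, via Leading Eigenvector Dynamics Analysis
(LEiDA) — with a synthetic-cohort generator that plants known states and
dynamics so every stage of the pipeline can be validated against ground
truth.

## Who this is for

Researchers analysing parcellated resting-state BOLD time series
(timepoints × regions tables) who want time-resolved functional
connectivity states and covariate-adjusted group comparisons of their
dynamics, with a fully reproducible, testable pipeline.

## The method

For regions n = 1..N with band-limited signals, the instantaneous phase
θ<sub>n</sub>(t) comes from the Hilbert analytic signal. At each volume the
phase-locking matrix

&nbsp;&nbsp;dPL(t)[n, p] = cos(θ<sub>n</sub>(t) − θ<sub>p</sub>(t))

summarizes pairwise synchrony, and its leading eigenvector **V₁**(t) — the
dominant whole-brain synchrony pattern — splits regions into two phase
communities by sign. Eigenvectors pooled across subjects are clustered
with spherical k-means; the number of states k is selected by the Dunn
index over a sweep (default k = 5..10). Per subject and state the pipeline
computes

- **fractional occupancy** P(state) — fraction of volumes in the state,
- **mean lifetime** — mean uninterrupted visit duration (× TR, in s),
- **switch-conditional transition probabilities** Q[i, j] = P(next = j |
  current = i, switch) — 20 directed transitions for k = 5.

Centroids are interpreted by Spearman correlation with canonical 7-network
membership maps (Bonferroni 0.05/7), and group differences are tested by
ANCOVA (partial F for group, controlling age, sex, handedness), with
Benjamini–Hochberg FDR within metric families, BIC-approximated Bayes
factors, and partial Spearman correlations for exploratory
brain–behaviour associations.

## Worked example

Simulate a two-group cohort (10 per group, 105 regions, 240 volumes at
TR = 2 s) whose groups differ only in planted state occupancies, then run
the full pipeline:

```r
library(leidar)
library(dplyr)

cfg <- cohort_config(
  n_per_group = 10,
  dynamics = list(
    patient = occupancy_dynamics(c(0.136, 0.157, 0.198, 0.233, 0.277) / 1.001),
    control = occupancy_dynamics(c(0.185, 0.175, 0.205, 0.228, 0.207))
  ),
  n_regions = 105, n_volumes = 240, tr = 2, seed = 42
)
cohort <- simulate_cohort(cfg)
run <- run_pipeline(cohort, k_min = 5, k_max = 5, n_restarts = 10, seed = 42)

glance(run$states)
#> # A tibble: 1 × 6
#>       k  dunn inertia n_pooled metric  seed
#>   <int> <dbl>   <dbl>    <int> <chr>  <int>
#> 1     5 0.119    367.     4760 cosine    42

run$stats$states |>
  filter(metric == "occupancy") |>
  select(state, mean_1, mean_2, F, p, p_fdr, bf10)
#> # A tibble: 5 × 7
#>   state mean_1 mean_2       F        p   p_fdr     bf10
#>   <int>  <dbl>  <dbl>   <dbl>    <dbl>   <dbl>    <dbl>
#> 1     1  0.192  0.302 19.8    0.000465 0.00232 1020.
#> 2     2  0.223  0.223  0.0168 0.899    0.899      0.226
#> 3     3  0.227  0.217  0.597  0.452    0.565      0.330
#> 4     4  0.182  0.126  5.26   0.0367   0.0917     4.52
#> 5     5  0.176  0.132  2.38   0.144    0.240      0.974
```

Here 4760 pooled eigenvectors (20 subjects × 238 retained volumes) form
five states; `mean_1`/`mean_2` are the control and patient group means of
fractional occupancy (states are numbered by descending pooled occupancy,
so state numbers need not match the planted order). The covariate-adjusted
ANCOVA flags a strong group difference in the occupancy of recovered
state 1 (F(1, 15) = 19.8, FDR-corrected p ≈ 0.002, BF₁₀ ≫ 10) — the
planted contrast — while states with equal planted occupancy stay null.
`run$network` holds the per-state network profiles (with the synthetic
atlas the planted communities are typically "Unclassified", as they
should be: its networks are random), `run$metrics` the long per-subject
metric table, and `write_results(run, dir)` exports everything as CSV plus
a JSON run report. `autoplot(run$states)`, `plot_state_metrics()`,
`plot_transition_differences()` and `plot_k_sweep()` visualize centroids,
metrics, transitions and model selection.

Ground-truth recovery at study scale, end to end:

```r
out <- recover_occupancy(c(0.185, 0.175, 0.205, 0.228, 0.207),
                         n_subjects = 20, seed = 1)
out$mean_occupancy[1]
#> [1] 0.1823529
```

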