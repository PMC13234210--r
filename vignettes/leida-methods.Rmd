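---
title: "Phase-locking brain states: model, estimation, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-locking brain states: model, estimation, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leidar)
```

## The method

Leading Eigenvector Dynamics Analysis (LEiDA) characterizes time-varying
whole-brain synchrony from resting-state BOLD signals. For each subject the
pipeline is:

1. **Band-pass filtering.** Each region's signal is demeaned and filtered to
   the slow hemodynamic band (default 0.01–0.1 Hz) with a 2nd-order
   Butterworth filter applied forward and backward (`signal::filtfilt`).
   Zero-phase filtering matters: a causal filter would shift every
   instantaneous-phase estimate by a frequency-dependent lag.
2. **Instantaneous phase.** The analytic signal of each region is computed
   in the frequency domain (the Hilbert-transform construction), and
   θ~n~(t) is its argument.
3. **Phase-locking matrix.** At each volume, dPL(t)[n, p] =
   cos(θ~n~(t) − θ~p~(t)). Because cos(a − b) = cos a cos b + sin a sin b,
   dPL(t) is exactly the rank-2 matrix **cc**ᵀ + **ss**ᵀ with
   **c** = cos θ(t), **s** = sin θ(t). `eigenvector_series()` exploits this:
   the leading eigenvector is obtained from the 2×2 Gram matrix of
   [**c** **s**], exactly and without an N×N eigendecomposition.
4. **Leading eigenvector.** V₁(t) captures the dominant synchrony pattern;
   its sign splits the regions into two phase communities. Eigenvectors are
   sign-ambiguous, so a fixed convention (mean ≤ 0, first nonzero entry
   negative on exact ties) is applied — without it, k-means sees every
   pattern twice, once per sign.
5. **Clustering.** Eigenvectors pooled over all subjects are clustered with
   spherical k-means (cosine distance, k-means++ seeding, best of 20
   restarts, max 500 iterations, relative tolerance 1e-6). Eigenvectors are
   directions, which is why cosine distance is the default; Euclidean
   k-means (`stats::kmeans`) is available as an option. The number of
   states is selected by sweeping k (default 5–10) and maximizing the Dunn
   index — minimum single-linkage between-cluster distance over maximum
   within-cluster diameter, on Euclidean distances of the unit-norm rows
   (monotone in cosine distance on the sphere). Dunn ties break toward
   smaller k; states are renumbered by descending pooled occupancy (stable
   sort on ties).
6. **Dynamic metrics.** Per subject: fractional occupancy (fraction of
   frames per state), mean lifetime (mean maximal-run length × TR), and the
   switch-conditional transition matrix (next-state probabilities given
   that a switch occurs; the diagonal is structurally zero and defined rows
   sum to 1). Undefined entries — unvisited states, rows with no exits —
   are stored as missing and excluded pairwise from group statistics.
7. **Network mapping.** Each centroid is Spearman-correlated with binary
   membership vectors of a 7-network atlas; significance at the Bonferroni
   threshold 0.05/7 ≈ 0.007. State labels concatenate significantly
   positively correlated networks in descending ρ.
8. **Group inference.** Per metric, an ANCOVA adjusts the two-group
   comparison for age, sex and handedness (education optionally added as a
   sensitivity analysis): the group effect is the partial F test of
   `value ~ group + covariates` against the covariate-only model, with
   df = (1, n − p). Occupancy and lifetime p-values are Benjamini–Hochberg
   corrected within each 5-state family; the 20 directed transitions are
   reported uncorrected and flagged exploratory (an optional BH column is
   included). Bayes factors use the BIC approximation
   BF₁₀ = exp((BIC₀ − BIC₁)/2), a deterministic default; exploratory
   brain–behaviour associations use partial Spearman correlations
   (residualized ranks, t-approximation with df reduced by the number of
   covariates).

### Lifetime conventions

Published mean lifetimes below the repetition time cannot arise from the
run-length × TR convention (its minimum is one TR), so the convention
evidently varies across reports. `lifetimes()` therefore exposes three
conventions — `runlength_times_TR` (default, the literal reading),
`runlength_minus_one_times_TR`, and `volumes` — and the package never uses
absolute lifetimes as recovery targets.

## The synthetic cohort generator

No public dataset accompanies this kind of study, so validation rests on a
generator that plants known ground truth at every stage.

**Planted states** are two-community sign patterns over N regions: regions
in community A oscillate in phase, anti-phase to community B. When a
subject follows pattern **p** without noise, dPL(t) = **pp**ᵀ is rank 1 and
V₁(t) = ±**p**/‖**p**‖ exactly — the generator realizes the model
assumption that the analysis estimates. Community-A sizes are spread over
10–42% of regions: distinct sizes keep states mutually distinguishable
(pairwise |cosine| < 0.95), and capping below half keeps every pattern's
mean safely negative. A pattern with a near-zero mean sits on the boundary
of the eigenvector sign convention, and under noise its frames flip sign
unstably and split into two antipodal clouds — capping at 42% removes this
failure mode.

**Signals.** x~n~(t) = cos(2π·0.05·t·TR + φ~n~(t) + ε) + η with the carrier
at 0.05 Hz (inside the analysis band), φ~n~ ∈ {0, π} according to the
active state's pattern, von Mises phase noise with concentration κ = 4
(circular SD ≈ 0.5 rad), and Gaussian amplitude noise with SD 0.2. These
defaults make clustering nontrivial while leaving recovery reliable.

**Dynamics.** Two modes separate occupancy recovery from transition
recovery. *Occupancy mode* cuts the scan into fixed-dwell blocks whose
states are drawn i.i.d. from a target occupancy vector π, so the planted
occupancy is exactly the categorical probability. *Markov mode* draws
geometric dwells (per-volume stay probability) and, on each switch, the
next state from a row of a switch-conditional matrix Q. The default mean
dwell is 4 volumes (8 s at TR = 2 s), inside the dwell range reported for
phase-locking states and short enough that a 240-volume scan contains ~60
independent state visits, which keeps per-subject occupancy estimates
informative.

**Covariates** (age, sex, handedness, education) are drawn independently of
the dynamics, so covariate-adjusted tests are exactly calibrated under the
null. Group differences enter only through π or Q; the generator cannot
distinguish this mechanism from alternatives (e.g. group differences in
noise), and does not try to.

### What the generator does not emulate

Scanner drift and motion, hemodynamic response variability, spatial
autocorrelation of real parcellations, 1/f noise, and any image-space
artefact. Passing recovery tests therefore demonstrates correctness of the
estimation pipeline under its own model assumptions, not robustness to real
acquisition confounds.

## Numerical and design choices

- **Band edges** default to 0.01–0.1 Hz; the low edge matches the usual
  preprocessing high-pass. Both are configurable, and results near the band
  edges depend on them.
- **Edge trimming**: the Hilbert transform distorts phases at series
  boundaries, so the first and last retained volume are dropped by default
  (`trim_edges = 1`).
- **Degenerate inputs**: zero-variance regions raise an error naming the
  region; empty label sequences raise an empty-input error; coincident
  clusters give Dunn 0; all-singleton clusterings return an infinite Dunn
  sentinel with a warning; rank-deficient ANCOVA designs raise a
  collinearity error naming the aliased columns.
- **Determinism**: every stochastic stage takes an explicit seed, and
  per-subject seeds are derived from the master seed, so identical
  configurations reproduce bit-identical cohorts and results.
- **Dunn at scale** is O(M²) in the pooled frame count and is accumulated
  blockwise (default 1024 rows per block), never materializing the distance
  matrix.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle or
planted truth:

- Leading eigenvectors against a shifted power-iteration oracle (N ≤ 6);
  the rank-2 fast path against the generic symmetric eigensolver; the Dunn
  index against an all-pairs brute force (M ≤ 200); BH adjustment against a
  hand-computed step-up.
- **Frame recovery**: on slow-switching cohorts (mean dwell 10 volumes) at
  default noise, ≥ 95% of pooled frames match their ground-truth state
  after optimal cluster matching, across 5 seeds. Frames at switch
  boundaries are intrinsically ambiguous — the analytic signal interpolates
  the phase jump — so frame accuracy decreases as dwells shorten (roughly
  84% at the default 4-volume dwell, 61% at 2 volumes). This also means
  switch-conditional transition estimates taken from clustered labels are
  inflated toward uniform by spurious boundary switches, a documented
  limitation of frame-level state estimation rather than of the metric.
- **Occupancy recovery** at study scale: a 20-subject cohort planted with a
  published five-state occupancy profile, run end to end (synthesis →
  filtering → phases → eigenvectors → k-means at k = 5 → matching),
  recovers the State-1 mean occupancy within ±0.02. With ~60 i.i.d. dwell
  blocks per scan the across-subject mean has sampling SD ≈ 0.011 per
  state, so ±0.02 is a ~2σ band for each state individually; the suite
  asserts State 1 plus the mean absolute error of the full profile.
- **Transition recovery**: the aggregate switch-conditional matrix pooled
  over 20 ground-truth label streams of pipeline length (238 frames,
  stay = 0.25) recovers every planted entry within ±0.05.
- **Model selection**: cohorts whose subjects each dwell in a single
  planted state (removing boundary bridges that defeat the single-linkage
  Dunn numerator) select k = 5 from a 2–10 sweep. On mixed within-scan
  sequences the Dunn curve is noise-dominated and model selection is
  unreliable — worth knowing when interpreting Dunn-selected k on real
  data.
- **Statistical calibration**: the group ANCOVA's type-I error on null
  cohorts (identical dynamics, 1000 label-level replicates) lies in
  0.05 ± 0.02, and power at a published State-1 occupancy effect
  (0.136 ± 0.045 vs 0.185 ± 0.053, n = 20 per group, 500 replicates)
  exceeds 0.8. These replicates simulate at the label/metric level: the
  quantity under test is the inference layer, and the signal-synthesis and
  clustering stages are validated separately by the recovery experiments.

## Known limitations

- The mapping from anatomical regions to canonical networks is an input
  table; the synthetic atlas stands in for it during testing and a real
  lookup table can be dropped in unchanged.
- The BIC Bayes factor is one of several reasonable choices and can differ
  substantially from prior-based Bayes factors; treat printed BF₁₀ values
  as ordinal evidence summaries.
- Clustering-stability analysis (split-half, bootstrap) is not provided.
- Frame-level accuracy near state switches is bounded by the time
  resolution of the analytic signal, not by the clustering.
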