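---
title: "Dynamic connectivity states and topological variability: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic connectivity states and topological variability: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynconn)
```

# Overview

`dynconn` implements a complete dynamic functional network connectivity
(dFNC) analysis for independent-component (IC) time courses, of the kind
used to compare resting-state brain dynamics between a patient group and
controls. The stages are:

1. **Motion QC and time-course cleaning** — Jenkinson framewise
   displacement with rule-based exclusion, then per-component detrending,
   despiking, zero-phase Butterworth low-pass filtering and motion-parameter
   regression.
2. **Tapered sliding-window connectivity** — per window, a taper-weighted
   covariance is regularised by an L1-penalised precision (graphical lasso),
   inverted, converted to correlation and Fisher-z transformed.
3. **State clustering** — k-medians (L1 distance) over all windows of all
   subjects, with silhouette-based selection of the number of states, and
   four temporal properties per subject: fractional windows, mean dwell
   time, number of transitions, transition likelihood.
4. **State modularity** — Louvain community detection with consensus
   clustering on each state centroid; Newman–Girvan Q.
5. **Dynamic topology** — per window, binary graphs over a sparsity grid;
   global/local/nodal efficiency, clustering coefficient, characteristic
   path length and small-world indices; AUC over the grid; coefficient of
   variation (CV) across windows.
6. **Group inference** — covariate-adjusted permutation tests with BH-FDR
   families, and Spearman partial correlations for clinical associations.

A Markov-switching multivariate Gaussian simulator (`sim_config()`,
`generate_cohort()`) provides cohorts with full ground truth, so every
recovery claim made by the test suite is checked against planted structure.

# The model and its assumptions

Windowed connectivity assumes the IC time series are locally stationary at
the window scale: within a window of $w$ TRs the data are treated as draws
from a zero-mean Gaussian with a fixed covariance, and the sequence of
window covariances is summarised by a small number of recurring *states*.
The simulator makes exactly this assumption generatively: a hidden Markov
chain at timepoint resolution selects, at every TR, one of $K$
positive-definite covariance matrices; the observed vector is a draw from
that state's Gaussian plus white noise, slow drift and occasional spikes.

Because windows are 20 TRs long while the chain switches at single TRs,
many windows straddle a switch. Ground-truth labels at window resolution
are defined by majority vote over the timepoints a window covers
(`majority_vote_labels()`); ties break towards the lower state index. This
is the natural discretisation — real windows straddle switches too — and it
bounds attainable recovery: windows near a 50/50 mixture are genuinely
ambiguous.

# Stage parameters

| Parameter | Default | Meaning |
|---|---|---|
| `window_len` | 20 TR | window length (40 s at TR = 2 s) |
| `step` | 1 TR | window step; 170 timepoints give 150 windows |
| `taper_sigma` | 3 TR | Gaussian convolved with the rectangle |
| `lasso_penalty` | 0.1 | graphical-lasso L1 penalty on off-diagonal precision |
| `k` | `"auto"` (2–8) | states, silhouette-selected |
| `n_init` | 100 | k-medians restarts |
| sparsity grid | 0.10–0.35 by 0.01 | binarization thresholds |
| `n_random` | 100 | degree-preserving references per graph |
| `n_perm` | 10,000 | permutations per group test |
| CV | SD/mean | dispersion of per-window AUC |

**Window count.** `window_starts()` emits $\lfloor (T-w)/\text{step} \rfloor$
windows — deliberately $T - w$, not $T - w + 1$, so that 170 timepoints with
$w = 20$, step 1 give exactly 150 windows, the count the pipeline is
calibrated around. The final fully contained window is dropped; this is
documented on the function and recorded in every run manifest.

**Taper.** The taper is a length-$w$ rectangle convolved with a unit-area
Gaussian of $\sigma = 3$ TR, truncated to the central $w$ samples. As
$\sigma \to 0$ it tends to the plain rectangle; symmetry is enforced
exactly.

**Sparse precision.** The graphical-lasso problem
$\max_\Theta \log\det\Theta - \mathrm{tr}(S\Theta) - \lambda\|\Theta_{\text{offdiag}}\|_1$
is solved by an ADMM iteration whose $\Theta$-update is a closed-form
eigendecomposition step and whose $Z$-update soft-thresholds the
off-diagonal entries; the step size is residual-balanced and consecutive
overlapping windows warm-start each other. At the solution the off-diagonal
stationarity conditions $|(\Theta^{-1})_{ij} - S_{ij}| \le \lambda$ hold
(with equality on the support), which the tests check directly, along with
agreement with the inverse sample covariance in the $\lambda \to 0$ limit.
Correlations are clamped at $1 - 10^{-7}$ before `atanh`.

**Penalty policy.** `select_lasso_penalty()` implements cross-validated
selection (random half-splits of windows; precision fitted on the pooled
train covariance; mean Gaussian log-likelihood on held-out windows). One
property worth knowing: with step-1 overlapping windows, train and test
windows share samples and the mean test log-likelihood depends only on the
pooled test covariance, so the criterion is essentially flat in $\lambda$
and favours the unregularised end. Cross-validation is therefore most
meaningful with non-overlapping windows (and is tested in that regime); the
pipeline default is a fixed $\lambda = 0.1$, which also keeps runs fast and
deterministic.

**Covariate residualisation.** Age and sex effects are estimated on
subject-level edge means (one regression per edge across subjects, centred
covariates) and the same fitted effect is removed from every window of a
subject. This preserves each edge's grand mean and each subject's
within-subject dynamics — only between-subject covariate structure is
removed. Per-window residualisation was the alternative; it was rejected
because the covariates are subject-level constants, so per-window fits
estimate the same coefficients with extra noise.

# State clustering choices

k-means with the L1 distance is implemented as true k-medians: assignment
by nearest centroid in L1, centroid update by component-wise median, so the
fitted centroids *are* the medians of their member windows (the tests
verify this to 1e-10). The best of `n_init` random restarts by total L1
cost is kept; empty clusters are re-seeded from the farthest point; states
are relabelled by descending occurrence so reports are deterministic.

The silhouette uses the same L1 distance on the full pooled distance
matrix; `select_k()` maximises the mean silhouette over the candidate
range. Windows in singleton clusters score 0.

Dwell time is reported in window units (the sampling unit of the label
sequences); the final, uninterrupted run counts towards the mean.
Transition likelihood rows with no outgoing pairs (a state never occupied,
or occupied only at the very end) are undefined and excluded from group
averages rather than imputed.

Centroids across window-size validation runs are matched by maximising
total Pearson correlation over one-to-one assignments (exhaustive over the
at-most-8! permutations).

# Modularity

Community detection runs on the state centroid rebuilt as a matrix with
negative Fisher-z values set to zero (absolute values are available via
`centroid_graph(..., negative = "abs")`). Q is Newman–Girvan weighted
modularity, written directly from its definition and checked against a
brute-force double sum; the Louvain pass itself uses igraph's
implementation behind `louvain_partition()`, whose returned Q is always
recomputed with the package's own `modularity_q()` (and falls back to the
single-module partition if a run ever scores below 0). Consensus
clustering (100 runs, co-assignment threshold $\tau = 0.5$, re-clustered
until all runs agree) resolves the stochasticity of single runs.

# Dynamic topology

Binarization keeps the `round(s · n(n−1)/2)` strongest strictly positive
edges (round half up; ties broken by the row-major edge index, making
profiles invariant to any strictly monotone transform of the z-values). If
a window has fewer positive edges than the target the window is flagged
but retained. Efficiency, clustering and path length are computed on
igraph shortest paths and verified exactly against a Floyd–Warshall +
triangle-count oracle on 200 random graphs per test run. $L$ averages over
finite-distance pairs only; the largest-component alternative was not
taken because flagged sparse windows would otherwise change the node set
between thresholds. $\gamma$, $\lambda$ and $\sigma = \gamma/\lambda$ use
Maslov–Sneppen degree-preserving references (10 × edge-count attempted
swaps; complete/empty graphs are their own reference).

The per-window metric-vs-sparsity curve is reduced to a trapezoidal AUC
(isolated undefined values interpolated from neighbours), and variability
across windows is the coefficient of variation of the AUC series. The
default CV is SD/mean — the standard definition; the literal reciprocal
(mean/SD) that sometimes appears in descriptions of this quantity is
implemented as `cv_over_windows(..., definition = "mean_over_sd")` so both
conventions are available. A constant series has CV 0; a series varying
around a zero mean is undefined under SD/mean and marked as such.

# Group inference

Permutation tests residualise the metric on an intercept plus covariates,
take the difference of group means of residuals as the statistic, and
permute group labels (residualise-then-permute; Freedman–Lane was the
considered alternative and matters little for subject-level covariates).
Two-sided p-values use the add-one convention
$p = (1 + \#\{|T^\ast| \ge |T|\})/(1 + B)$, so $p \ge 1/(B+1)$ always.
BH-FDR runs within declared families — occupancy, dwell time, and the
nodal-CV family — exactly as the comparison plan specifies; global-CV
metrics are reported uncorrected. Spearman partial correlation ranks all
variables, residualises the ranked x and y on ranked covariates, and uses
the t approximation on the residual correlation.

# The simulator: what it emulates and what it does not

Defaults (chosen once; they are the package's reference conditions):
10 subjects per group, 20 components, 170 timepoints at TR = 2 s; state 1
with two modules at within-module correlation 0.7, state 2 uncorrelated;
control transitions with stay probabilities 0.990/0.995 and a patient-like
group at 0.980/0.996, giving long-run state-1 occupancy near 34% vs 17%
(echoing the occupancy contrast such studies report) while keeping every
transition row estimable at 170 timepoints; observation noise SD 0.2;
drift amplitude 0.5 (linear + 0.005 Hz sinusoid); spike probability 0.005
per sample at 6 noise SDs; smoothed mean-reverting motion scaled to mean
FD ≈ 0.1 mm, with an optional high-motion flag (≈ 0.3 mm) to exercise
exclusion.

The simulator emulates the *covariance* structure the analysis assumes —
it does not emulate hemodynamic autocorrelation, spatial maps, scanner
drift spectra, or physiological noise. Consequently, passing recovery
tests show the pipeline recovers planted window-scale covariance states
under realistic noise, not that any particular clinical dataset contains
such states.

Two empirical observations from the synthetic experiments are worth
stating. First, at timepoint-level stay probability 0.95 (mean dwell ≈ one
window length) a large fraction of windows straddle switches, and the
0.15-Hz low-pass filter at TR = 2 s additionally smears transitions across
neighbouring windows; the silhouette can then prefer an intermediate
"mixture" cluster. The state-recovery experiments therefore run the dFNC
stage on the generated component time courses directly, which is also how
their setups are defined. Second, CV-based $\lambda$ selection is
uninformative with overlapping windows (see above).

# Numerical choices and degenerate inputs

- ADMM tolerance 1e-5 (relative to $\|S\|_F$), 2000-iteration cap,
  residual-balanced step size; non-convergence is an error naming the
  window.
- The despike baseline is an intercept + linear trend +
  $\lfloor n/30 \rfloor + 1$ sine/cosine pairs; residuals are scaled by
  MAD × 1.4826; values beyond $c_1 = 2.5$ robust SDs are compressed by the
  tanh rule with cap $c_2 = 4$. A flat series (MAD 0) is returned
  unchanged.
- The Butterworth low-pass is applied forward–backward (zero phase) with
  even-reflection padding of min(n−1, 100) samples; the digital
  (bilinear-transform) design is steeper near Nyquist than the analog
  magnitude curve, so stop-band leakage is below the analog bound.
- FD uses the Jenkinson RMS formulation with an 80-mm sphere at the
  isocenter; rotations are radians on disk, degrees only in QC thresholds.
- Modular covariance builders shrink towards the identity in steps of 0.01
  until positive-definite, recording the shrinkage; an infeasible
  combination (still non-PD at shrinkage 0.9) errors.
- Windowing problem sizes used by the test-suite recovery experiments:
  20 subjects × 150 windows (pooled 3000 windows), 15–20 components,
  20–30 k-medians restarts for selection experiments (the pipeline default
  remains 100).

# Known limitations

- The stage order detrend → despike → filter → regress is fixed; the
  despike/detrend order inside AFNI-style cleaning is not uniquely
  documented and the listed order is adopted.
- The filter is low-pass only; a band-pass variant (adding a high-pass
  edge) is a plausible alternative not currently exposed.
- With heavily overlapping windows the λ cross-validation criterion is
  flat (see above); prefer the fixed-λ policy there.
- Re-applying the full preprocessing pipeline is not byte-idempotent: any
  real filter re-attenuates content near its cutoff on a second pass. The
  linear stages (detrend, nuisance regression) are exactly idempotent and
  tested as such.
- Permutation tests assume exchangeability of residualised subjects under
  the null; with strong covariate-group confounding, residualisation
  before permutation is an approximation (the type-I error simulation in
  the test suite covers the exchangeable case).
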