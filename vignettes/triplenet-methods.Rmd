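---
title: "Methods: static and dynamic functional network connectivity in the triple-network model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: static and dynamic FNC in the triple-network model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triplenet)
```

## Scope and model

`triplenet` analyses interactions among a small set of network nodes —
by default seven independent-component time courses spanning the
triple-network model: the default-mode network (DMN: PCC, MPFC, IPL), the
left and right executive-control nodes (LECN, RECN) and the salience
network (SAN: insula, dACC). Two complementary views are computed:

* **Static FNC**: full-scan Pearson correlation between node time courses,
  Fisher r-to-z transformed (`compute_sfnc`). The z transform
  (atanh) approximately normalizes the sampling distribution; values with
  |r| at the boundary are clipped to 1 - 1e-7 so z stays finite.
* **Dynamic FNC**: tapered sliding-window correlations
  (`sliding_window_connectivity`) summarized two ways — recurring
  *brain states* found by k-means over windows, and a *multilayer network*
  whose community structure is optimized jointly over all windows.

Group inference is a GLM per derived measure with covariates, with
Benjamini–Hochberg FDR applied within declared measure families, plus
Pearson brain–behavior correlations.

## Sliding-window construction

Windows of `window_length = 22` TRs slide in steps of 1 TR; a time course
of T = 169 samples therefore yields `169 - 22 + 1 = 148` windows (the
closed-window convention `W = floor((T - L)/step) + 1`). Each window is
weighted by a taper built by convolving a rectangle of the window length
with a discrete Gaussian of `sigma = 3` TRs (truncated at ±4σ), cut back
to the window length and normalized to sum 1 (`make_taper`). As σ → 0 the
taper tends to the uniform window, and a single full-length uniform window
reproduces the static FNC exactly — a useful consistency check that the
test suite asserts. Within a window the correlation is the weighted
Pearson correlation with the taper as weights; it is invariant to affine
rescaling of each node's signal.

## Time-course post-processing

Stages run in fixed order (each preserves the data shape):

1. **Polynomial detrending** (`detrend_polynomial`, degree 3): least-squares
   removal of linear, quadratic and cubic trends; residuals are orthogonal
   to the polynomial basis.
2. **Nuisance regression** (`regress_nuisance`): intercept + regressors
   (e.g. six realignment parameters) and, by default, their temporal
   derivatives. The derivative is the backward first difference with the
   first sample set to 0 — stated explicitly so tests are exact.
3. **Low-pass filtering** (`lowpass_filter`, cutoff 0.15 Hz): 5th-order
   Butterworth applied forward–backward (zero phase). The filter family
   and order are a design choice; they are standard for resting-state
   pipelines and fully testable through the frequency response. Because
   a forward–backward pass with zero initial conditions leaves edge
   transients, the series is extended by odd reflection before filtering
   and trimmed afterwards; a constant series then passes through unchanged
   to numerical precision.
4. **Despiking** (`despike`): samples deviating from the column median by
   more than `z_thresh = 3` robust standard deviations (1.4826 × MAD) are
   replaced by linear interpolation between the nearest non-spike
   neighbours (edge spikes take the nearest non-spike value). Detection is
   deterministic and the operation is idempotent. A column with more than
   half its samples flagged is rejected as unusable.

## Brain states: k-means and temporal statistics

Windows from all subjects are pooled (each window vectorized as the upper
triangle of its z matrix), clustered by k-means with squared Euclidean
distance — 500 Lloyd iterations and 150 restarts by default, each restart
initialized by greedy k-means++ — and assignments are split back per
subject. Pooled clustering is the established convention for this
analysis; it guarantees group-comparable state labels.

The number of states is chosen by an elbow criterion
(`select_k_elbow`): for each candidate k the ratio
R(k) = (mean distance of windows to their assigned centroid) /
(mean pairwise distance between centroids) is computed, and the selected
k maximizes the discrete curvature `R(k-1) - 2 R(k) + R(k+1)`. At the two
ends of the candidate grid the missing neighbour is treated as continuing
the curve flat, so the curvature reduces to a one-sided difference there.
Without this extension the smallest candidate could never be selected,
yet data with exactly two well-separated clusters should yield k = 2; the
extension leaves all interior selections unchanged.

Per subject, the state sequence over windows is summarized by:

* **RF** (reoccurrence fraction): fraction of windows in each state
  (sums to 1);
* **DT** (dwell time): mean length of maximal runs of each state, in
  windows (0 for unvisited states; seconds = windows × TR on request);
* **TTN**: number of adjacent window pairs with different states.

Cluster labels are arbitrary, so all downstream comparisons are
label-permutation invariant.

## Multilayer community structure

Each window becomes a layer of a multilayer network: intra-layer edges are
the window's connectivity weights; copies of the same node in temporally
adjacent layers are coupled with weight ω (ordinal coupling). The quality
of a community assignment g is the multilayer modularity

Q = (1/2μ) Σ_{ijlr} [ (A_ijl − γ_l P_ijl) δ_lr + δ_ij ω_jlr ] δ(g_il, g_jr),

with A the intra-layer weights, P the per-layer Newman–Girvan null
(P_ijl = k_il k_jl / 2m_l), γ_l the resolution, ω_jlr the interlayer
coupling, and μ half the total edge strength (intra-layer plus coupling).
`modularity_Q` evaluates this sum directly; the test suite checks it
against an independent naive double-loop implementation to 1e-12 and
against analytic single-layer values (two disconnected triangles: optimal
Q = 0.5; everything in one community: Q = 0).

Optimization (`genlouvain_optimize`) is a generalized Louvain scheme over
node-layer copies: phase 1 sweeps copies in seeded random order, moving
each to the community with the largest modularity gain (tolerance 1e-10;
ties keep the current community, which prevents label churn); phase 2
aggregates communities into super-nodes; the phases repeat until no move
improves Q. Q is non-decreasing across phases (asserted at run time). On
every test network small enough for exhaustive enumeration (≤ 9
node-layer copies, Bell-number search), the best of 20 seeded runs attains
the global optimum. Because individual runs vary with the sweep order,
analyses use an ensemble of 50 runs (`run_ensemble`) and average the
derived indicators.

From the ensemble, **module allegiance** P_ij is the relative frequency —
over all runs and all layers jointly — with which nodes i and j share a
community (averaging the per-run layer fractions across runs gives the
same number). **Integration** summarizes cross-network mixing: node-level
integration is the mean allegiance between a node and all nodes of other
networks; network-level integration averages node values within a
network; network-pair integration is the mean allegiance between two
networks' nodes. The unnormalized allegiance mean is used (no null-model
normalization); this is documented rather than assumed, since normalized
variants exist in the literature.

Defaults: γ = 1, ω = 1, and negative windowed correlations are clipped to
zero before modularity (the Newman–Girvan null is ill-defined for signed
weights); an `absolute` policy is available, and the choice is recorded in
the output metadata. All three are exposed in `pipeline_config`.

## Group statistics

* `glm_group_compare`: OLS of a measure on intercept + group indicator +
  covariates (age, sex as 0/1, education, mean framewise displacement);
  the reported t and two-sided p belong to the group coefficient with
  n − p residual degrees of freedom. With no (or constant) covariates it
  reduces exactly to the pooled two-sample t. A zero-variance measure
  returns t = 0, p = 1 with a warning instead of aborting a family.
* `ttest_two_sample`: pooled-variance Student t (raw samples or summary
  statistics). Pooled rather than Welch is the package default because it
  is the field convention for demographic tables and reproduces the worked
  example frozen in the test suite (t = 0.018 for a near-identical
  motor-score row) to the printed precision.
* `chi_square_2x2`: Pearson chi-square without continuity correction
  (Yates' correction would report 0.000 where the uncorrected statistic
  gives 0.001 for the worked sex-by-group example).
* `fdr_bh`: Benjamini–Hochberg step-up within declared families. With 7
  nodes and k = 4 states the families are: 21 static edges; 4 RF; 4 DT; 7
  node-level integrations; 3 network integrations; 3 network-pair
  integrations; TTN and modularity Q are single values per subject and
  remain uncorrected. Family sizes are asserted at pipeline run time.
* `pearson_correlation`: r with a t-based two-sided p on n − 2 degrees of
  freedom, reported uncorrected, computed within groups for measures that
  survive FDR.

## The synthetic generator

Because no public recording accompanies the analysis protocol, the
package ships a generator whose defaults *are* the study conditions, so
every downstream stage has a recoverable target.

**Latent states.** Four covariance templates (`default_state_specs`)
emulate the canonical recurring connectivity profiles: (1) globally
sparse; (2) strong coupling within and between DMN and ECN; (3) tightly
positive everywhere; (4) DMN coupled with the left ECN node. Templates
are specified as block target-correlation matrices and repaired to valid
unit-diagonal SPD matrices by eigenvalue clipping at 1e-6 followed by
re-normalization (`make_state_covariances`; idempotent once SPD, with an
explicit failure after 100 steps). The free correlation values were fixed
once so that the four templates are *mutually well separated* in Fisher-z
space (all pairwise distances comparable and large against the sampling
noise of a 22-TR windowed correlation, which is ≈ 0.25 per edge): state 3
is a global equicorrelation at 0.6, and state 4 couples DMN+LECN at 0.7
while being mildly anticorrelated (−0.3) with the remaining nodes — the
familiar default-mode/task-positive opposition. Without that separation
the state-2/state-4 templates differ on only four edges and merge into a
single cluster, which no model-order criterion can be expected to
resolve.

**State dynamics.** One latent state per window index (window w of a
T-sample series starts at sample w; sample t takes the state of window
min(t, W)), so window labels have unambiguous ground truth. The sequence
is a first-order Markov chain constructed from a target occupancy π and a
mean dwell d: T[s,t] = a·π_t for s ≠ t and T[s,s] = 1 − a(1 − π_s), with
a = 1/(d·Σ_s π_s(1 − π_s)). This chain has π as its *exact* stationary
law (the initial state is drawn from π) and its aggregate mean run length
is exactly d; the empirical occupancy therefore converges to the target,
and the mean run length is recovered within 10% at 10^4 windows. An
alternative construction that fixes every state's self-transition at
1 − 1/d cannot hold the stationary law at a skewed π (its stationary
occupancies deviate by several percentage points), so occupancy recovery
was preferred. A dwell of 1 means "switch every window"; for skewed
occupancies very small dwells are infeasible (the rarest state would need
a negative self-transition) and are rejected with an explicit error.

**Defaults as study conditions.** N = 7 nodes, T = 169 samples, TR = 2 s
(so 148 windows), k = 4 states, occupancies (0.42, 0.19, 0.22, 0.17), and
observation noise sd 0.2 added to unit-variance signals. The default mean
dwell is 50 windows (100 s at TR = 2): with 22-TR windows, state
persistence must comfortably exceed the window length or nearly every
window straddles a transition and becomes a mixture of covariances —
under those conditions four "well-separated" states do not exist in the
windowed data at all. With these defaults the elbow criterion recovers
k = 4 from 40 simulated subjects across independent seeds (verified over
10 seeds, not tuned to one).

**Cohorts.** `simulate_cohort` draws group labels, covariates, derived
measures with additive group shifts, and behavior scores linear in a
designated measure plus Gaussian noise — the structure needed to verify
GLM calibration (type-I error at nominal α), power (a 1-pooled-SD shift
on one of 21 edges is detected after family-wise FDR in well over 90% of
replicates at n = 60 per group) and null behavior of the correlation
stage.

**What the generator does not emulate:** hemodynamics, spatial maps,
scanner drift or motion artifacts beyond generic polynomial trends and
spikes, non-Gaussian noise, and between-subject heterogeneity of the
state templates. Passing tests therefore demonstrate correctness of the
estimators and the recoverability of known ground truth under the stated
conditions — not robustness to every property of real recordings.

## Problem sizes and numerical choices

The test suite runs the full pipeline on reduced problem sizes chosen to
exercise every stage while staying quick: e.g. 12 subjects × 60 samples
(39 windows), 2–10 optimizer runs, 5 k-means restarts; the heavier
recovery experiments (40 subjects × 148 windows for model-order
selection; 100-replicate power studies) run in the acceptance checks.
Key numerical constants: correlation clipping at 1 − 1e-7 before atanh;
SPD floor 1e-6; Louvain move tolerance 1e-10 with keep-current
tie-breaking; BH adjustment via the step-up formula (monotone, capped at
1). Deterministic seeding throughout: every stochastic function takes a
seed, derives independent sub-seeds for replicates/subjects/runs, and
restores the caller's RNG state.

## Known limitations

* The elbow criterion compares centroid geometry, not model evidence; for
  weakly separated or heavily mixed states it is conservative (tends to
  merge close states) — by design it reports the number of *well
  separated* clusters.
* The Newman–Girvan null with the `clip_zero` policy discards negative
  connectivity; the `absolute` option keeps magnitude but conflates signs.
  Signed null models are out of scope.
* Integration is the unnormalized allegiance mean; comparisons across
  networks of very different sizes should keep that in mind.
* The GLM assumes homoscedastic Gaussian residuals; no robust or
  permutation variant is provided.
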