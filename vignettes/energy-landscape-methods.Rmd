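---
title: "Energy-landscape analysis of brain-state dynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-landscape analysis of brain-state dynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(energyscape)
```

`energyscape` implements the full analysis chain used to describe
resting-state brain dynamics as movement on an energy landscape: a pairwise
maximum-entropy model is fitted to binarized network activity, the model's
energy function defines brain states (basins of local minima) and their
hierarchy (a disconnectivity graph), a Metropolis random walk simulates
state dynamics, and per-subject transition statistics and intrinsic neural
timescales feed group comparisons, symptom correlations and mediation
analysis. A synthetic-cohort generator with planted effects makes every
stage testable against known ground truth. This vignette documents the
models, the numerical choices, and the reasoning behind the design
decisions that the method descriptions leave open.

## The pairwise maximum-entropy model

Continuous signals from $N$ network nodes (here $N = 7$, named after the
seven canonical resting-state networks) are binarized per timepoint:
activity $\sigma_i^t = +1$ when node $i$'s signal at time $t$ strictly
exceeds the mean across the $N$ nodes at that timepoint, $-1$ otherwise.
The pairwise maximum-entropy (Ising) model assigns each activity pattern
$V = (\sigma_1, \ldots, \sigma_N)$ an energy

$$E(V) = -\sum_i h_i \sigma_i \;-\; \tfrac{1}{2}\sum_{i}\sum_{j} J_{ij}\,\sigma_i \sigma_j,$$

with basal activities $h_i$ and symmetric zero-diagonal couplings $J_{ij}$,
and appearance probability $P(V) = e^{-E(V)} / \sum_\ell e^{-E(V_\ell)}$.
This is the least-structured distribution matching the first- and
second-order moments $\langle\sigma_i\rangle$ and
$\langle\sigma_i\sigma_j\rangle$ of the data.

Fitting is by gradient ascent on the log-likelihood, which reduces to
moment matching: $h_i \mathrel{+}= \epsilon(\langle\sigma_i\rangle -
\langle\sigma_i\rangle_m)$ and similarly for $J_{ij}$, with model moments
recomputed exactly by enumeration of all $2^N$ patterns at each step.
Defaults: learning rate $\epsilon = 0.2$, zero initialization, convergence
when the largest absolute moment gap falls below $10^{-8}$, iteration cap
$5 \times 10^5$ (non-convergence is flagged, not thrown). Because the
pairwise family is an exponential family, moment matching is maximum
likelihood and the solution is unique; fits recover generating parameters
from exact moments to machine-level precision, and from $5\times10^4$
samples to within sampling noise. Enumeration bounds practical model size
at $N \le 20$; pseudo-likelihood approximations for larger $N$ are out of
scope.

Moments are pooled across the subjects of a group by row-stacking their
binarized series — the group-level fit used throughout, since single-subject
scans are too short for a stable fit. A warning is emitted when moments
come from fewer than $2^{N-1}$ timepoints. (The source protocols state this
rule ambiguously; we read it as $2^{N-1}$ rather than $2^N - 1$, and the
threshold is configurable.)

Fit quality is the proportion of the Kullback–Leibler divergence of the
independent (first-order) model removed by the pairwise model:
$(D_1 - D_2)/D_1$ where $D_k$ is the divergence of the empirical pattern
distribution from the fitted $k$-th-order model. KL divergences are taken
as empirical-from-model, in nats; this direction makes $D_k$ the expected
log-likelihood gap, the standard choice in this literature. When
$D_1 < 10^{-12}$ (e.g., a uniform empirical distribution) the ratio is
flagged undefined rather than reported.

Two further numerical conventions: the independent fit
$h_i = \operatorname{atanh}\langle\sigma_i\rangle$ clamps means at
$1 - 10^{-9}$ in magnitude so saturated nodes stay finite, and pattern
probabilities are normalized with a log-sum-exp shift. Binarization ties
(signal exactly equal to the threshold) map to $-1$: deterministic, and a
measure-zero event for real-valued data. Pattern codes fix node 1 as the
least-significant bit with $-1 \mapsto 0$, $+1 \mapsto 1$.

## Landscape: minima, basins, disconnectivity

Patterns form a hypercube graph (adjacent iff they differ at exactly one
node). A local minimum has energy strictly below all $N$ neighbours; minima
are labelled `a`, `b`, … in ascending energy (ties by pattern code), and
their basins — the brain states `A`, `B`, … — are found by steepest
descent: from any pattern, move to the neighbour with the largest energy
drop until a minimum is reached. We use steepest descent with a
lowest-code tie-break rather than "first smaller neighbour found" because
it is order-independent and reproducible; the greedy variant depends on an
unspecified neighbour ordering. Patterns at which two or more neighbours
tie exactly for the steepest drop are flagged saddle-ambiguous and are
excluded from state sequences (the counts are logged); with
continuous-valued parameters such exact ties essentially never occur.
Equal-energy neighbours count as non-descending.

The disconnectivity graph summarizes the minima hierarchy. The defining
procedure lowers a threshold through the sorted energy values, removes
patterns above it, and records when minima become disconnected. We compute
the same quantity in one ascending pass: patterns are inserted in
increasing energy order into a union-find structure and united with
already-inserted neighbours; when two components each containing a minimum
first merge, the inserted pattern's energy is the merge energy. The test
suite verifies exact agreement with a literal implementation of the
descending-threshold loop. Note that a shallow minimum can be removed by
the descending threshold while deeper minima remain connected; the
procedure therefore runs until all *remaining* minima are isolated. Trees
are exported as merge tables (in `hclust` convention) and as Newick
strings with merge energies as node heights.

## Brain-state dynamics

Dynamics on the landscape are simulated by a Metropolis–Hastings single-flip
walk: propose one of the $N$ neighbours uniformly, accept with probability
$\min[1, e^{E(V_i) - E(V_j)}]$. Downhill moves are always accepted; uphill
moves remain possible, so the walk is not trapped. A rejected proposal
repeats the current pattern and counts toward the dwell time — the standard
MCMC convention (the method descriptions are silent on this point). The
stationary distribution is exactly the model's Boltzmann distribution;
detailed balance is asserted analytically over all neighbour pairs in the
tests, and a $10^6$-step walk reproduces the exact distribution to within
total-variation distance $0.01$. Defaults: $10^5$ steps, the first $100$
discarded, random initial pattern, fully seeded.

Trajectories (simulated) or binarized subject series (empirical) are
classified into brain states by basin membership, run-length compressed
into dwell episodes, and summarized by transition counts. Frequencies are
normalized per step of the *uncompressed* sequence so that short empirical
scans (~175 steps) and long simulated walks ($10^5$ steps) are on one
scale. Concatenated subjects never contribute cross-boundary transitions.

Indirect transitions between the two most stable states are counted with
path templates: an unordered endpoint pair plus an ordered list of interior
blocks, each a set of admissible states. On the run-compressed sequence, a
match is a segment bounded by the two endpoints whose interior runs split
into consecutive nonempty groups drawn from the blocks in order. The three
canonical templates for a six-state landscape are `A–C/D–B` (one block
{C,D}), `A–[C/D–E/F]–B` (block {C,D} then block {E,F}), and `A–C–F–B`
(block {C} then {F}). Two open readings were settled as follows: the
bracketed notation is read in its strictest ordered-block sense (an
unordered "visits both sets" variant would also match, e.g., `A E C B`,
blurring the distinction between templates); and both traversal directions
are counted, with block order reversed for the return direction, because
the dash notation is symmetric (a direction flag restricts to forward-only).
Frequencies divide by all steps, including direct `A–B` steps — the
denominators are not conditioned on path type.

## Intrinsic neural timescale

For each signal (node, region or voxel) the sample autocorrelation function
is estimated with the standard biased estimator (bounded by 1, one time bin
per TR), and the intrinsic timescale is the TR-scaled area of the initial
positive lobe:

$$\mathrm{INT} = \mathrm{TR} \times \sum_{k=1}^{k^*-1} \hat\rho(k), \qquad
k^* = \min\{k \ge 1 : \hat\rho(k) \le 0\}.$$

The lag-0 term (identically 1) is excluded by default — including it only
shifts every value by one TR — and "hits zero" is read as the first lag at
or below zero; both choices are configurable flags because the verbal
definition ("the sum over the initial period of positive values") admits
either reading. A signal with nonpositive lag-1 autocorrelation has
INT $= 0$. The estimator is location/scale invariant, strictly increasing
in AR(1) persistence, and agrees with an independent simulate–estimate–
integrate oracle to within ±15% at $\phi = 0.8$. Spatial smoothing of
voxel maps is deliberately out of scope at node resolution.

## Group statistics

- **Two-sample comparisons**: pooled-variance t tests
  ($df = n_a + n_b - 2$, matching the reported df patterns) with Cohen's
  $d$ on the pooled SD.
- **Two-way ANOVA**: the four-group design is coded as two binary factors
  (diagnosis₁ × diagnosis₂); interaction tested with type-II sums of
  squares, appropriate for the unequal cell sizes, and reported with
  partial $\eta^2 = SS_\mathrm{int}/(SS_\mathrm{int}+SS_\mathrm{err})$.
  Both the factor coding and the $\eta^2$ variant are assumptions — the
  alternatives (group × condition coding, classical $\eta^2$) are one-line
  changes on the returned sums of squares.
- **Correlations**: Pearson with t-based p; partial correlation as the
  correlation of OLS residuals with $df = n - k - 2$.
- **Multiple comparisons**: Bonferroni for confirmatory families, BH
  step-up FDR for exploratory (map-wise) families, following the usual
  division of labour.
- **Mediation**: three OLS fits give the paths $\alpha$ (x→m), $\beta$
  (m→y | x), total $\gamma$ and direct $\gamma'$; the indirect effect is
  $\alpha\beta$ and $\gamma = \gamma' + \alpha\beta$ holds exactly.
  Percentile confidence intervals from seeded case-resampling bootstrap
  (default 5000 replicates); the percentile method was chosen over
  bias-corrected variants as the simplest interval with correct nominal
  behaviour in the planted-chain tests.

The tests verify nominal behaviour empirically: type-I error of the t test
across 1000 null replicates, FDR control under a null/alt mixture, and
recovery of a planted $(\alpha, \beta, \gamma' = 0)$ chain at $n = 200$.

## The synthetic cohort generator

Real cohorts for this kind of study are restricted-access clinical rsfMRI
data; the generator stands in for them with planted, known effects.

Each group is a ground-truth Ising model. The default study uses one base
landscape for all four groups — a seven-node model with uniform(−0.3, 0.3)
fields and uniform(−0.6, 0.6) couplings from a fixed seed, selected so the
landscape has exactly six local minima with robust depth margins (the
margins must survive refitting from cohort-sized data), two clearly deepest
states, negligible probability on the two uniform patterns (invisible to
per-timepoint-mean binarization), and nonzero traffic along all three
canonical templates. Group landscapes are depth-scaled copies (deeper for
the ASD-like group, shallower for the ADHD-like groups), which multiplies
all energies without moving any minimum.

Subjects are simulated with the package's own Metropolis walker, which by
construction realizes the fitted model class exactly; two parameters
control dynamics beyond the landscape:

- **Dynamical speed** (`steps_per_tr`): how many Metropolis steps the
  network evolves between recorded timepoints. Faster groups produce
  signals with shorter intrinsic timescales *and* more completed indirect
  transitions per recorded step, while the stationary pattern distribution
  — and hence the fitted landscape — is untouched. This single mechanism
  is what makes "unstable local activity → frequent indirect transitions"
  a causal, recoverable chain rather than two unrelated plants. Default:
  TD/ASD 2, comorbid 4, ADHD 6 steps per TR.
- **Subject jitter**: log-normal per-subject factors on speed (sd 0.5) and
  landscape depth (sd 0.15) provide the within-group variability that
  correlations and mediation run on; optional entry-wise Gaussian jitter
  on $(h, J)$ exists but defaults to 0 so group fits recover the group
  model exactly.

Binary patterns become continuous signals by adding i.i.d. Gaussian noise
of SD $1/\mathrm{snr}$ around ±1 (default snr 8, at which re-binarization
recovers well over 95% of entries). Symptom scores are planted linearly on
each subject's *realized* indirect-transition frequencies (measured against
the group's ground-truth landscape), with slopes and noise chosen so
within-group correlations fall in the 0.4–0.7 band typical of reported
symptom–dynamics associations; sample sizes (30 per group) and series
length (175 timepoints at TR 2 s) match a single-site pediatric rsfMRI
study. An optional `mediation_plant` adds an explicit $(x, m, y)$ linear
chain with requested coefficients for isolated testing of the mediation
stage. All randomness flows from one master seed through documented
stream-splitting (sub-seeds drawn once from the master seed).

What the generator deliberately does **not** emulate: hemodynamic
convolution (binarization would largely destroy it), scanner noise
structure, motion artifacts, preprocessing effects, or voxel-level spatial
structure. Passing tests therefore demonstrate the correctness of the
*analysis machinery* and the recoverability of effects under the model's
own assumptions — not robustness to the full noise structure of real
rsfMRI data.

## The pipeline and cross-group state matching

`run_full_study()` chains the stages: per group, binarize → pool → fit →
landscape → simulated walk; per subject, empirical state dynamics and a
timescale map; at cohort level, group tests (Bonferroni per feature
family), symptom correlations and bootstrap mediations. Failing subjects
are excluded with a logged reason; a group losing half its subjects aborts
the run. Results serialize to tidy CSVs plus one machine-readable JSON.

Because minima labels are per-landscape, states are matched across groups
before any cross-group comparison: greedy maximum-|similarity| assignment
between minimum patterns (Pearson correlation of the ±1 vectors, ties by
energy rank), with signed similarities reported — a globally sign-flipped
landscape matches its mirrored partners with similarity −1 rather than
being forced into a false positive match. Fits on cohort-sized data
occasionally produce a spurious extra minimum or miss the shallowest one;
matching is therefore done against a *reference landscape* (the reference
group's fit by default, or an explicit `reference_model` — in synthetic
studies, the ground-truth base model), and unmatched minima lose their
basin rather than silently shifting every letter. Features that reference
a state absent from a group's fit are reported as missing for that group.

The default mediation analysis pools the ADHD-like and control groups
(case–control mediation): the group contrast contributes most of the
variance in the local timescale, so the pooled $x \to m$ path reflects the
planted mechanism with adequate power at $2 \times 30$ subjects, whereas
the within-group path at $n = 30$ is dominated by the counting noise of
175-step path frequencies. This mirrors how the planted effect is actually
expressed at the study's data size; a within-group analysis is one
configuration line away.

## Problem sizes and determinism

The shipped tests run the complete stack at the study's native size
(4 × 30 subjects × 175 timepoints × 7 nodes, $10^5$-step walks, $10^6$
steps for sampler stationarity checks, 200-replicate timescale medians,
1000-replicate type-I simulations) in well under a minute each; every
stochastic step takes an explicit seed and is bit-reproducible. The
`scripts/acceptance.R` entry point re-runs the main computations from
scratch for any seed and writes the headline quantities as JSON.

## Known limitations

- Exact enumeration restricts the model to $N \le 20$ nodes (practically
  $N \le 10$ for repeated fitting); this matches network-level analyses
  but not voxel-level ones.
- The per-timepoint-mean threshold cannot represent the two uniform
  patterns (all-active / all-inactive); the default base model keeps their
  probability negligible, but analyses of landscapes where such patterns
  matter should use the per-node-temporal-mean mode (provided, since the
  verbal description "the whole-brain average signal" is ambiguous between
  the two).
- Empirical per-subject path frequencies at ~175 timepoints carry Poisson
  counting noise of the same order as realistic between-subject effects;
  group-level inferences are well-powered, subject-level ones are noisy.
  The simulated (group-level) route exists precisely because rare
  transitions are undersampled in short scans.
- Mediation is OLS-based with percentile bootstrap; no causal
  identification beyond the standard mediation assumptions is claimed.
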