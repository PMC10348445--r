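# energyscape

Energy-landscape analysis of brain-state dynamics in R.

Resting-state fMRI studies of neurodevelopmental conditions (ASD, ADHD, and
their comorbidity) increasingly describe whole-brain dynamics as movement on
an *energy landscape*: network activity is binarized, a pairwise
maximum-entropy (Ising) model is fitted to it, and the model's energy
function defines a small set of *brain states* — basins around local energy
minima — between which the brain dwells and transitions. Atypical dynamics
(e.g., overly frequent indirect transitions between the two most stable
states) can then be linked to local neural instability (short *intrinsic
neural timescales*) and to symptom severity through correlation and
mediation analysis.

`energyscape` implements that entire chain as a tested, reusable R package
for anyone analysing multivariate neural time series at network resolution:

- **Model fitting** — binarization, exact moment computation, first-order
  and pairwise maximum-entropy fits by gradient ascent, and fit accuracy
  as the KL-divergence ratio $(D_1 - D_2)/D_1$.
- **Landscape** — exhaustive energy enumeration, local minima, basin
  assignment by steepest descent, and disconnectivity graphs (merge
  energies via an ascending union-find pass, verified against the literal
  descending-threshold procedure).
- **Dynamics** — Metropolis–Hastings random walks with acceptance
  $\min[1, e^{E(V_i)-E(V_j)}]$, dwell times, transition matrices, and
  indirect-transition path templates such as `A–C/D–B`, `A–[C/D–E/F]–B`
  and `A–C–F–B`, counted in both directions.
- **Timescales** — intrinsic neural timescale as the TR-scaled area of the
  autocorrelation function up to its first zero crossing, per node or per
  network.
- **Group statistics** — pooled t tests with Cohen's d, type-II two-way
  ANOVA with partial η², Pearson/partial correlations, Bonferroni and
  BH-FDR control, and percentile-bootstrap mediation (α, β, γ, γ′, α×β).
- **Synthetic cohorts** — a generator that plants group differences,
  symptom couplings and a full timescale→dynamics→symptom mediation chain
  with known ground truth, so every downstream stage is testable without
  access to restricted clinical data.

The model: each binary activity pattern $V = (\sigma_1,\dots,\sigma_N)$,
$\sigma_i \in \{\pm 1\}$, has energy

$$E(V) = -\sum_i h_i\sigma_i - \tfrac12\sum_i\sum_j J_{ij}\sigma_i\sigma_j,
\qquad P(V) \propto e^{-E(V)},$$

with $h$ and $J$ fitted so the model's moments match the data's. See the
methods vignette (`vignettes/energy-landscape-methods.Rmd`) for every
modelling and numerical choice.

## Worked example

Fit one group of the default synthetic study and inspect its landscape:

```r
library(energyscape)

cohort <- generate_cohort(default_study_spec(seed = 42))
td_ids <- cohort$manifest$subject_id[cohort$manifest$group == "TD"]
group  <- run_group_landscape(cohort$series[td_ids], study_config())

group$fit$accuracy_pct
#> [1] 98.07413
group$minima[, c("label", "code", "energy")]
#>   label code    energy
#> 1     a   16 -3.868974
#> 2     b   99 -3.379939
#> 3     c  111 -3.379228
#> 4     d  105 -3.145545
#> 5     e   28 -3.042711
#> 6     f   70 -2.353861
```

The pairwise model explains 98.1% of what the independent model misses,
and the fitted landscape has six local minima — six brain states, with
state `a` clearly deepest. Now the full study — landscapes per group,
state matching, per-subject dynamics and timescales, and the statistics:

```r
res <- run_full_study(cohort, default_study_config(seed = 42))

res$fit_summary
#>      group accuracy_pct        d1         d2 converged n_minima
#> 1       TD     98.07413 0.9934355 0.01913226      TRUE        6
#> 2      ASD     98.41685 1.2958191 0.02051482      TRUE        7
#> 3     ADHD     95.96684 0.4971858 0.02005231      TRUE        6
#> 4 ASD_ADHD     97.78495 0.7462741 0.01653035      TRUE        7

subset(res$group_tests, feature == "freq_ACDEFB")
#>       feature    group reference          t df       p_raw   cohens_d p_bonferroni
#> 4 freq_ACDEFB      ASD        TD -2.2051033 58 0.031425478 -0.5693552   0.09427643
#> 5 freq_ACDEFB     ADHD        TD  2.8939077 58 0.005352708  0.7472038   0.01605812
#> 6 freq_ACDEFB ASD_ADHD        TD  0.6109546 58 0.543616661  0.1577478   1.00000000

res$mediations[[1]]$result
#> <mediation_result> n=60, 5000 bootstrap replicates
#>             estimate    lower     upper
#> alpha        -0.0003  -0.0005   -0.0002
#> beta        876.3548 459.2645 1329.5650
#> gamma         0.0208  -0.9787    0.3539
#> gamma_prime   0.2681  -0.6392    0.5856
#> indirect     -0.2473  -0.5085   -0.1025
```

Reading the output: the ADHD-like group shows a significantly elevated
frequency of the indirect `A–[C/D–E/F]–B` transition relative to controls
(t(58) = 2.9, Bonferroni p = 0.016, d = 0.75) — the planted group effect.
The mediation decomposes hyperactivity scores on the pooled ADHD + TD
sample: a shorter intrinsic timescale of the dorsal-attention node predicts
more indirect transitions (α < 0), which predict higher symptom load
(β > 0); the indirect effect α×β is significantly negative (95% CI
[−0.51, −0.10]) while the direct path γ′ is not distinguishable from zero —
the planted causal chain, recovered end to end.

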