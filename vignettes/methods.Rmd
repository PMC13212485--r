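---
title: "Hybrid boosted ensembles with evidence fusion for SC-CO2 solubility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid boosted ensembles with evidence fusion for SC-CO2 solubility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ghef)
```

## The problem

Equilibrium solubility of lipophilic drugs in supercritical carbon dioxide
(SC-CO2) governs the feasibility of supercritical micronization and
extraction processes, but measuring it requires slow, specialized
high-pressure experiments. This package models solubility, in the working
unit (g/L) × 10, as a function of four descriptors: temperature (K),
pressure (MPa), molecular weight (g/mol) and melting point (°C). Two
gradient-boosted tree learners — a classic exact-split variant (`gb`) and a
histogram-binned variant (`hgb`), both fitted with xgboost under squared
error — are tuned by a population metaheuristic and fused by two
complementary strategies: an optimized weighted average and Dempster–Shafer
(DS) evidence combination. Percentile-bootstrap prediction intervals
quantify uncertainty.

## The synthetic study design

Real multi-compound SC-CO2 solubility compilations are rarely redistributable,
so all testing runs on a synthetic replica of a four-drug factorial design:

* Tacrolimus (MW 804.03, MP 128 °C), Rifampin (822.95, 185 °C) and
  Teriflunomide (270.21, 230 °C) on the full grid
  {308, 318, 328, 338} K × {12, 15, …, 30} MPa (28 cells each);
* Sirolimus (914.172, 183 °C) on a 19-cell subset of
  {313, …, 328} K × {12.5, …, 25} MPa.

The Sirolimus layout deserves a note: published summaries of such designs
report only per-variable means and standard deviations (321.4211 /
5.6318 K and 19.4736 / 3.8541 MPa for a 19-run design), not the runs
themselves. An exhaustive search over all 5-cell removals from the 4 × 6
grid (with the two solubility-anchoring corners pinned) shows exactly one
subset reproduces all four statistics to below 1e-4; `default_compounds()`
uses that subset, so `summarize_dataset()` recovers the published cells
from generated data. The total is 103 records; the original compilation
had 110, whose per-compound decomposition was never published.

The noiseless response surface is Chrastil-style log-linear,

$$\ln y = a \,\ln \rho^*(T, P) + b/T + c,$$

with a smooth density proxy
$\rho^*(T,P) = \mathrm{logistic}((P - 7.38)/5)\cdot(304.1/T)$ — a logistic
rise in pressure centred at the CO2 critical pressure, scaled by inverse
reduced temperature. The proxy is not an equation of state; downstream code
relies only on its sign structure (increasing in P, decreasing in T,
positive), which is what the package tests. Per compound, $a$ is fixed from
the pressure-range log-ratio at mid temperature scaled by 0.8 (pressure
carries 80% of the dynamic range), then $(b, c)$ solve the two-anchor
system pinning the surface to the compound's published solubility minimum
at the (min T, min P) corner and maximum at (max T, max P). For all default
compounds the resulting surface is strictly increasing in both axes over
the design, so the anchors are its grid extremes.

Noise is multiplicative lognormal, $y = y_0 e^{\varepsilon}$,
$\varepsilon \sim N(0, \sigma^2)$ with $\sigma = \ln(1 + \mathrm{cv})$ and
cv = 0.05 by default — solubilities span two orders of magnitude and must
stay positive, and 5% relative scatter is typical of static gravimetric
measurements. One RNG stream is derived per compound from the master seed,
so adding a compound never perturbs the others.

What the generator does *not* emulate: retrograde (non-monotone in
pressure) solubility regions, co-solvent effects, heteroscedastic
instrument error, and inter-laboratory offsets between the four source
designs. Tests passing on this fixture therefore demonstrate the machinery
(tuning, fusion, calibration), not chemical validity on real systems.

## Base learners and their search space

The boosting mathematics is delegated to xgboost (`tree_method = "exact"`
for `gb`, `"hist"` for `hgb`), single-threaded and seeded for bit
reproducibility. Three hyperparameters are tuned: learning rate in
[0.01, 0.3], maximum depth in [2, 74] (`gb`) or [2, 139] (`hgb`) — the
published search-space upper bounds — and boosting rounds in [50, 300].
The rate and round intervals are the package's own choice, set to contain
the published tuned optima (0.05, 0.145, 147) with headroom. Optimizer
positions live in the unit cube; `decode_position()` maps them affinely
onto the intervals, rounding integer dimensions half-up, and clips
out-of-range coordinates first, so every position decodes to a valid
configuration.

`reference_config()` provides fixed non-tuned members (rates 0.05 / 0.145,
147 / 150 rounds, depths 3 / 6): the published tuned values where printed,
mid-range choices where not. These serve as the plain single-model variants
and as frozen members wherever tuning would be nested inside another
resampling loop.

## The optimizer

The Electric Eel Foraging Optimization (EEFO) algorithm is a
population metaheuristic in which an energy factor schedules the shift
from exploration to exploitation, and each candidate replaces its
incumbent only if strictly better (greedy selection; ties keep the
incumbent; non-finite objective values count as +Inf and are rejected
rather than crashing the run). The published description fixes the
selection rule, the energy-factor semantics (E > 1 explores, E ≤ 1
exploits, E decays with iteration) and the run settings (population 30,
200 iterations, patience 20); the movement operators themselves are not
printed. The package's variant, isolated behind `propose_candidate()` so a
different faithful port is drop-in:

* energy factor $E = 4u(1 - t/T_{\max})$, $u \sim U(0,1)$ — initial
  exploration probability 3/4, guaranteed exploitation late;
* exploration: interacting move $v = x_r + \alpha (x_r - x_i)$,
  $\alpha \sim N(0,1)$, with the reference a 50/50 mix of a random peer
  and a random point of the box;
* exploitation, chosen uniformly: resting (uniform local perturbation,
  radius 10% of the box scaled by $1 - t/T_{\max}$), hunting
  ($x_{best} + r(x_{best} - x_i)$) and migrating
  ($x_i + r(x_{best} - x_r)$);
* all candidates clipped into the box.

Early stopping uses an absolute improvement tolerance of 1e-8 with
patience 20 (the patience is the published setting; the tolerance is
ours). Tuning objectives are the mean k-fold CV RMSE with folds fixed once
per run; the space midpoint is seeded into the initial population, which
makes "tuned never worse than the midpoint incumbent" a theorem rather
than a hope. The desk profile (population 15, 50 iterations) is the
default for tests and examples; `profile = "paper"` restores 30/200.

## Ensemble fusion

**Weighted averaging.** `fit_weights()` minimizes fitting-set RMSE of
$\sum_m w_m \hat y_m$ over the probability simplex. The optimizer searches
$[0,1]^M$ and repairs by normalization (repair, not penalty, keeps weights
interpretable as relative member importance); the unit vectors and the
uniform vector are seeded into the population, so the fitted ensemble is
provably no worse on the fitting set than its best member. Weights are fit
on out-of-fold CV predictions of the members (never on resubstitution
predictions, which would reward overfit members).

**DS evidence fusion.** The published framework names belief,
plausibility and ignorance but not a concrete construction for continuous
regression outputs; the package's scheme is the minimal one delivering
exactly those outputs while staying fully testable against enumeration
oracles:

* the solubility axis is discretized into K = 20 equal bins spanning the
  training target range padded by 5% per side;
* each model contributes a Gaussian centred at its prediction with its
  validation RMSE as bandwidth, integrated per bin, renormalized, and
  discounted by a reliability $r = 1/(1 + \mathrm{RMSE}/\sigma_y)$ capped
  at 0.999 (the cap preserves nonzero ignorance mass $1 - r$);
* focal elements are restricted to singletons plus the ignorance set,
  a family closed under Dempster's rule, keeping combination exact and
  O(K²);
* Dempster's rule folds the per-model masses (per-record conflict is
  reported as a diagnostic; total conflict is an explicit error);
* the pignistic transform (ignorance split uniformly over bins) extracts
  the fused point value, which therefore always lies inside the frame.

Discretization costs up to half a bin width of resolution; the refinement
test verifies the fused estimate converges to the shared prediction of
agreeing sharp sources as K grows.

## Evaluation statistics

RMSE, R², MAPE, prediction-interval coverage (closed intervals — boundary
counts as covered) and the fractional error FGE = MAPE/100 are implemented
as printed in the source formulas; the proportionality of MAPE and FGE is
property-tested. A zero observed value makes MAPE/FGE a hard error rather
than an epsilon-fudge: near-zero solubilities are exactly the regime where
the percentage error explodes, and silently patching the denominator hides
it. Kruskal–Wallis screening wraps `stats::kruskal.test` (tie-corrected H,
chi-square p on g − 1 df), with the all-values-identical degenerate case
returning H = 0 by convention with a flag; an independent brute-force rank
oracle cross-checks it in the tests. Feature screening groups solubility
by each feature's design levels (compound identity for the two molecular
descriptors, which are constant within compound).

Local attribution is a self-contained LIME-style surrogate (hermetic — no
external explanation framework): Gaussian perturbations around the record
scaled by background population SDs, exponential kernel on standardized
distance (width 0.75·√4), weighted least squares on standardized features.
A feature's score is its standardized-scale coefficient (raw slope ×
feature SD, in solubility units); zero-variance background features are
flagged and scored 0.

## Uncertainty

`bootstrap_pi()` implements percentile-bootstrap prediction intervals:
B resamples of the training set with replacement, full refit per
replicate, empirical 2.5/97.5 percentiles (type-7 linear interpolation
between order statistics, so bounds are bit-reproducible) of each target
record's B predictions. B = 1000 is the full-scale setting; the desk
profile uses B = 200. Member hyperparameters are frozen from an initial
fit by default — nesting a full metaheuristic tuning inside every
replicate is disproportionate to what the interval measures, and the
published total runtime implies the original study did not nest it either;
a flag enables the expensive variant. Inside replicates, ensemble weights
are refit on the out-of-bag records (~37% of the training set), falling
back to out-of-fold CV when the out-of-bag set is degenerate. Replicate
seeds derive per-replicate from the master seed, so growing B never
changes earlier replicates. Targets outside the training feature hull are
flagged `extrapolated`: bootstrap intervals only capture sampling and
refit variability inside the sampled domain.

The calibration study in the tests and the acceptance script uses the
standard 103-record fixture (noise cv 0.05), an 80/20 compound-stratified
split, the weighted ensemble with reference members and desk-profile
weight fitting, B = 200, averaged over 10 master seeds. Percentile
bootstrap intervals are approximate — they reflect refit variability, not
irreducible observation noise — so empirical coverage of a nominal 95%
level is accepted within ±10 percentage points; observed values sit near
92%.

## Problem sizes and numerical choices

The default test and example scale is: the 103-record fixture, desk
optimizer profile (15 × 50), 5 CV folds, B = 200 bootstrap replicates,
10-seed calibration averages. Full-scale presets (30 × 200, B = 1000)
are available via `profile = "paper"` and `bootstrap_config()`. Other
fixed choices: simplex and mass-function sum tolerances 1e-12; Dempster
total-conflict guard at 1 − 1e-12; reliability cap 0.999; DS frame padding
5%; train/test split default 0.2 stratified by compound with
largest-remainder quotas; round-half-up when decoding integer
hyperparameters (R's default round-half-even would bias the grid).

## Known limitations

* The generator's physics is a monotone surrogate; retrograde solubility
  and co-solvent effects are out of scope, so conclusions about real
  systems require real data.
* DS fusion resolution is bounded by the frame's bin width; predictions
  are clamped to the frame by construction.
* With only two base learners the weighted ensemble can at best match the
  better member when their errors are strongly correlated; gains appear
  when error patterns are complementary.
* Bootstrap intervals ignore observation noise on future measurements;
  they are confidence-flavoured rather than fully predictive, which the
  ±10-point calibration tolerance acknowledges.

## A worked run

```{r, eval = FALSE}
fixture <- generate_dataset(generator_config(seed = 1))
report <- run_pipeline(run_config(data = fixture, variant = "ghef_w",
                                  seed = 1,
                                  bootstrap = bootstrap_config(replicates = 200)))
report
```

`compare_variants()` fits all six variants (`gb`, `hgb`, tuned `gbef` /
`hgef`, fused `ghef_w` / `ghef_d`) on one shared split and tabulates the
statistics sorted by test RMSE; see the README for a printed example.
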