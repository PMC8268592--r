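---
title: "Inferring metabolite-dependent flux regulation with scour"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring metabolite-dependent flux regulation with scour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scour)
```

## The inference problem

Allosteric and substrate-level regulation couple the rate of a metabolic
reaction to the concentrations of a handful of metabolites — the
reaction's *controllers*. The stoichiometric topology of metabolism is
well charted, but which metabolites control which fluxes is unknown in
most organisms, and testing a single candidate interaction in the lab is
expensive. Given dynamic metabolomics and fluxomics data (concentration
and flux time courses), `scour` triages the combinatorial space of
candidate interactions: for every flux it predicts whether that flux is
fully determined by one, two or three named metabolite concentrations.

The framework is stepwise. Step *n* enumerates, per flux, every
*n*-metabolite set containing the reaction's primary substrate
(`choose(m - 1, n - 1)` sets over `m` metabolites), classifies each with a
machine-learning model trained for that order, and removes positively
identified fluxes from the later — combinatorially much larger — steps.
Removal is the point of the stepwise design: on the bigger reference
network the three-controller pool shrinks from 324 to 108 candidates when
the lower-order fluxes are identified first.

## Power-law dynamics and the two reference networks

Test data are generated from networks whose rates follow Biochemical
Systems Theory: every non-constant flux is a product of power laws,

$$v_j = k_j \prod_i x_i^{g_{ji}},$$

with rate constants $k_j \sim U[0.1, 1]$, kinetic orders
$g_{ji} \sim U[0.1, 1]$ for activators (the substrate always among them)
and $g_{ji} \sim U[-1, -0.1]$ for inhibitors. Two fixed benchmark
networks ship with the package: `reference_network("smaller")` (6
metabolites, 6 reactions; one 1-controller, two 2-controller and two
3-controller fluxes) and `reference_network("bigger")` (10 metabolites,
10 reactions; three of each order). Both start with a constant,
unregulated influx `v1` and mix activation and inhibition. The exact
regulatory edge lists are package fixtures chosen to realise those
per-order counts with a biologically plausible mixture of feedback and
feed-forward loops.

Simulation integrates $\dot x = S\,v(x)$ with `deSolve::lsoda` at
relative tolerance 1e-8 (absolute 1e-10) over a horizon of $T = 10$ time
units, storing a dense 451-point grid that is subsampled to the working
sampling frequency. Initial conditions are drawn uniformly from
$[0.1, 2]$ per metabolite. Random power-law kinetics can be globally
stiff — some draws drive a metabolite to zero for *every* initial
condition — so draws whose trajectories fall below a positivity floor of
1e-6 are rejected and redrawn, parameters included
(`sample_test_system()` packages this rejection loop). A test dataset is
15 time courses from independent admissible initial conditions sharing
one kinetic parameter set.

## Autogenerated training data

No real labelled data exist at the scale classifier training needs, so
training interactions are synthesised. Controller profiles are damped
sine waves

$$x(t) = C + A e^{-\lambda t} \sin(\omega t + \varphi),$$

with $A \sim U[0.1, 1]$, $\lambda \sim U[0, 0.5]$, 1–3 full oscillation
cycles over the horizon, random phase, and offset
$C \sim A + U[0.1, 2]$ — strictly positive by construction, with the
decaying-oscillation shape of transient metabolite dynamics. A *true
positive* of order $n$ computes a power-law flux (exponent magnitudes
$U[0.1, 1]$, the designated substrate exponent positive, others of random
sign) from exactly the $n$ stored profiles. *True negatives* come in
three constructions:

* **mismatch** — 1..$n$ stored profiles are replaced by fresh sines that
  took no part in the flux computation (the candidate set is simply
  wrong);
* **higher_order** — the flux is computed from $n+1$ or $n+2$ profiles
  but only $n$ are stored (the set is insufficient);
* **superset** — the flux is computed from fewer than $n$ profiles and
  the stored set is padded with inert decoys (the set is sufficient but
  not minimal — the confuser a later step meets whenever a lower-order
  flux escaped removal).

The three modes are mixed in equal proportion. Early versions used only
the first two; the superset mode was added because without it a single
missed two-controller flux floods the three-controller step with
superset false positives, and nothing in training teaches the classifier
that non-minimal sets are negatives.

Each stacking level receives its own independent set of 400 positives
and 400 negatives per step ("hundreds" of examples; the two sets share
no random draws, preventing metamodel leakage).

### Matching training to test structure

Two structural choices make the synthetic training distribution match
what the classifier sees at test time:

1. **Matched distortion.** Under a noisy run condition the training
   profiles receive exactly the test-data treatment: triplicate Gaussian
   noise, then the step's preprocessing (median collapse before step 1,
   Gaussian smoothing before steps 2–3).
2. **Multi-segment examples.** Each training example concatenates 15
   independently drawn profile segments driven by *one* shared power
   law — mirroring the 15 test time courses that share one kinetics. A
   single smooth trajectory makes almost any metabolite set look like
   it determines any flux (the state moves along a one-dimensional
   curve, so nearest neighbours in any projection are temporal
   neighbours); only across trajectories from different initial
   conditions does a wrong set betray itself by mapping the same input
   state to different flux values.

## Features

Step 1 (one controller) uses five scalar features of the (metabolite,
flux) pair:

* `f_spearman` — absolute Spearman rank correlation (a flux tracks its
  sole controller monotonically, whatever the kinetic order);
* `f_loglin_r2` — $R^2$ of the regression of $\log v$ on $\log x$,
  exact for a substrate-only power law and degraded by any hidden
  controller;
* `f_resid_ac` — lag-1 autocorrelation (floored at 0) of that
  regression's residuals: measurement noise leaves white residuals,
  while a hidden smooth controller leaves temporally structured ones —
  the omnibus test separating "noisy but sufficient" from "missing a
  controller" on noisy data;
* `f_resid_explained` — maximum over the *other* metabolites of the
  system of the simple-regression $R^2$ of those residuals on that
  metabolite's log-concentration. This is the targeted counterpart of
  `f_resid_ac`: a hidden controller whose contribution sits below the
  noise floor (kinetic order near the 0.1 boundary) is invisible to the
  omnibus autocorrelation, but regressing the residuals directly on the
  candidate culprit still finds it. Training examples carry a matched
  context: their hidden true controllers plus fresh decoy sines, padded
  to the system's metabolite count;
* `f_knn_loo_r2` — leave-one-out $R^2$ of a 3-nearest-neighbour
  regression, floored at 0 (multivalued relationships predict poorly).

Steps 2–3 use seven features of the candidate set $X$ and flux $v$:

* `g_uniqueness` — the functional-uniqueness score: after min–max
  normalising $X$, the mean $|\Delta v| / \mathrm{range}(v)$ over
  nearest-neighbour timepoint pairs closer than the median pairwise
  distance. If $X$ completely defines $v$, nearby input states must have
  nearby fluxes and the score is near zero.
* `g_subset_gap` — minimal uniqueness score among maximal proper subsets
  minus the full-set score (is every member needed?).
* `g_loglin_lackfit` — $\log_{10}(1 - R^2)$ of the regression of
  $\log v$ on $\log X$. Under power-law kinetics the flux of the true
  controller set is *exactly* log-linear, so this probes the
  hypothesised functional form directly; values are floored at 1e-9
  before the logarithm so occasional negative noisy measurements cannot
  break it, and the log scale spreads out the decisive region near
  $R^2 = 1$.
* `g_loglin_gain` — $\log_{10}$ of the $R^2$ improvement of the full
  set over its best maximal proper subset, floored at $10^{-12}$
  (adding a regressor can only raise $R^2$, so maximal subsets provably
  dominate the full subset search; the same monotonicity argument, in
  the opposite direction, justifies restricting `g_subset_gap` to
  maximal subsets). The log scale matters: network dynamics correlate
  the controllers of a real flux, so the raw improvement from the last
  controller can be of order $10^{-3}$ — far above the $10^{-12}$ of a
  genuinely inert decoy, yet invisible to distance-based learners after
  standardisation on a linear scale.
* `g_cor_min`, `g_cor_max` — extremes of the per-member absolute
  Spearman correlation with the flux.
* `g_partial_min` — minimum over members of the absolute Spearman
  correlation between that member and the residuals of a 3-NN regression
  of $v$ on the remaining members; an inert decoy explains nothing
  beyond the rest and drives this toward zero.

All features are invariant to positive rescaling of any input series
(rank statistics and min–max normalisation give the correlation,
bin-spread and uniqueness features full positive-affine invariance; the
log-linear features absorb multiplicative rescaling into the intercept
but are, by design, sensitive to additive shifts of a concentration's
zero point). Degenerate inputs — constant series, zero flux range — map
to all-zero features with a flag instead of erroring, so no candidate is
ever silently dropped. Pooled series entering the quadratic-cost
neighbour searches are thinned to at most 120 evenly spaced points for
orders 2–3 (360 for the cheaper order-1 set); denser sampling of 15
smooth trajectories adds cost, not information.

## The two-level stack

Four heterogeneous base learners are fitted on the level-1 feature
matrix: a random forest (200 trees) and a shallow neural network (one
hidden layer of 10 units, logistic output, weight decay 1e-3) as
regressors on the 0/1 label, plus a 5-nearest-neighbour classifier and a
linear discriminant classifier. Their four outputs (regressors clipped
to [0, 1]) are computed on the independent level-2 set, and a second
linear discriminant classifier — the metamodel — is fitted on those
4-vectors. Features are standardised with level-1 statistics everywhere.
The metamodel's class boundary is used as-is; no threshold is tuned. A
base learner that is unanimous on the level-2 set contributes a
within-group-constant column that carries no discriminant information;
such columns are dropped when fitting the discriminant (with a
majority-class fallback if none remain).

Hyperparameters (tree count, $k$, hidden units, linear rather than
quadratic discriminants) are package defaults recorded in the training
report; the framework's signal comes from the features and the matched
training distribution, not from tuning.

## Aggregation across test time courses

How evidence from the 15 test time courses is combined is an open design
choice. The package implements two modes; the default (`"auto"`,
currently identical to `"pooled"`) concatenates the time courses and
classifies each candidate once, with training examples built from
matching multi-segment profiles. Per-trajectory classification with a
majority vote (`"vote"`) is retained as an option but is strictly weaker
here: along one trajectory a flux is a single-valued function of almost
any candidate set (so the vote cannot separate confounded sets at
orders 2–3), and at order 1 a per-trajectory rank correlation loses,
under noise, the cross-trajectory slope-consistency information that the
pooled log-linear fit retains.

## Noise model and preprocessing

Measurement noise replaces each value $y_i(t_k)$ by draws from
$N(y_i(t_k),\ (\mathrm{CoV} \cdot y_i(t_k))^2)$, three replicates per
timepoint, applied to concentrations and fluxes alike. The studied
conditions are CoV ∈ {0.05, 0.15} at sampling frequencies of 50 or 15
timepoints. Negative draws are retained (no truncation is part of the
stated model); downstream features tolerate them. Before step 1 the
triplicates are collapsed by per-timepoint median; before steps 2–3 they
are averaged and smoothed with a moving Gaussian filter whose window
spans a quarter of the simulation time, with kernel SD a quarter of the
window (so ±2 SD fills it) and edge handling by renormalising the kernel
over available points — no padding data are invented. Whether replicates
should be smoothed individually is not settled; the default
mean-then-smooth can be switched to median-then-smooth via `combine` in
`smooth_collapse()`.

## Evaluation protocol

A candidate counts as a ground-truth positive only when its controller
set equals the flux's true controller set *and* the flux's true order
equals the step order. Accuracy, sensitivity, specificity, PPV and F1
are computed per step from the confusion counts; undefined ratios
(zero denominators) propagate as `NA` and are excluded from replicate
averages — so runs in which a true flux was removed at an earlier step
simply contribute nothing to the sensitivity mean, and F1 is undefined
whenever PPV or sensitivity is. `run_experiment()` holds the test data
fixed and repeats the autogenerate–train–classify–score cycle with
independent training seeds, reporting per-metric means with standard
errors. The comparison baseline (`random_baseline()`) calls each
candidate positive with probability one half under *oracle* removal of
lower-order fluxes — an advantage to the baseline — and its expected PPV
is the prevalence of true interactions among the candidates (10% at the
smaller network's two-controller step, for example).

## Problem sizes and reproducibility

Package defaults follow the study conditions: 400 training examples per
class per level, 15 test time courses, 15 pooled training segments.
The test suite exercises the full protocol at 3 training replicates per
condition, and `scripts/acceptance.R` runs 10; the per-replicate
protocol itself is identical at any replicate count. All randomness
flows from explicit integer seeds; identical seeds give byte-identical
prediction tables.

## What passing tests do and do not show

The synthetic generator emulates transient, oscillation-and-decay
metabolite dynamics driving multiplicative power-law kinetics, with
intensity-proportional Gaussian measurement error. Real metabolic data
differ in known ways: saturable Michaelis–Menten and Hill kinetics are
not power laws (the log-linear feature then probes an approximation, not
an identity), metabolite pairs can be near-collinear (an identifiability
problem no feature can resolve), sampling grids are rarely uniform, and
error is rarely exactly intensity-proportional. Published kinetic models
of real organisms are therefore consumed only as externally supplied
time-course tables (`read_timecourse()`, tidy or wide CSV) — the
package never re-simulates them — and performance numbers from the
reference networks should be read as upper bounds for biological data.
Reversible or saturable rate laws, steady-state flux-balance analysis,
and interactions of four or more controllers are out of scope.
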