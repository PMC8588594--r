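---
title: "Emulating multi-output disease trajectories with time-as-input forests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emulating multi-output disease trajectories with time-as-input forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t2demu)
```

## The emulation problem

A patient-specific simulator of type-2-diabetes progression maps a
10-field initial condition — sex, age, weight class, height class, a
weekly physical-activity pattern and per-meal macronutrient levels — to
26 weekly values of three clinically meaningful outputs: body mass index
β(t), fasting glucose γ(t) and the inflammation proxy TNF-α τ(t). The
simulator itself is a mixture of differential equations and agent-based
immune dynamics and is computationally heavy; the emulator's job is to
reproduce its input→output map cheaply enough for interactive use.

Of the standard emulation strategies for dynamic multi-output simulators
(a multivariate emulator over the stacked time points; hybrid statistical
models with Gaussian-process innovations; one-step-ahead Markovian
emulation; time as an additional regressor), this package implements the
last: the week index `t` joins the ten subject features as an eleventh
input, so one model per output covers the whole horizon and every row of
every trajectory contributes to training. The training table is long —
N = K·T rows for K subjects — which is exactly the regime (moderate
feature count, very many rows) where bagged regression trees are a strong
default, and where Gaussian processes become impractical because of the
cubic cost in N.

The emulator is therefore

$$\hat y^h(x, t) = \frac{1}{M}\sum_{m=1}^{M} T^h_m(x, t), \qquad
h \in \{\beta, \gamma, \tau\},$$

three independent forests of M = 50 trees (fit via `ranger`, single
threaded for reproducibility). Independent single-output forests are the
simplest faithful reading of a per-output tree average; the residual
cross-covariance between outputs is recorded on the model
(`residual_cov`) but not otherwise used. Tree hyperparameters beyond M
are the conventional regression defaults (`mtry` = ⌊√11⌋, minimum node
size 5), exposed as arguments for sensitivity analysis. Weeks outside
1–26 are predicted but flagged, since trees extrapolate by nearest
partition.

## The design space and its subsampling

The factor levels are fixed: 2 sexes × 5 ages × 3 weight classes × 3
height classes × 19 activity patterns × 27 diets = **46170** subjects.
The 19 arises because a sedentary subject (0 sessions/week) has no
duration or intensity; those two fields collapse to a single 0/0
sentinel, giving 1 + 3·3·2 = 19 activity patterns instead of the naive
24. Without the sentinel the grid would double-count physically identical
sedentary subjects.

Training subsets are selected by a Latin-hypercube-style design. A
maximin continuous LHS is meaningless on a purely categorical grid, so
the package realizes the same intent — marginal representativeness — by
stratified allocation: each of eight factors (the three activity fields
act as one composite 19-level factor) receives level counts proportional
to k within one unit, levels are matched across factors by seeded random
permutation, and duplicate subjects are repaired by swap moves that
provably preserve every marginal count. Samples are deterministic given
(grid, k, seed). The split into training and test sets is done at the
subject level — all 26 weeks of a subject fall on one side — because a
subject-level generalization claim is what the evaluation is about.

## The energy model

The surrogate and the diet optimizer share one energy-balance model.
Daily expenditure is TDEE = REE + AEE + TEF:

* **REE** via the Mifflin–St Jeor equation `10W + 6.25H − 5A ± offset`
  (+5 male, −161 female), on representative body measures: per-sex
  heights (male 165/175/185 cm, female 155/162.5/170 cm for
  short/average/tall) and per-class BMIs (17.5/22/27.5 for
  underweight/normal/overweight), with weight W = BMI·(H/100)².
  The classes are categorical in the design, so some numeric realization
  is unavoidable; these values are mid-range conventions and live in
  `energy_constants()`.
* **AEE** as a MET model averaged per day:
  `sessions · hours · (MET − 1) · W / 7`, MET 4 at 40 %VO₂max and 7 at
  60 %VO₂max (net of resting cost, hence the −1).
* **TEF** is 10 % *of calories ingested*. Under energy balance intake
  equals TDEE, so the balanced intake solves the fixed point
  `intake = (REE + AEE)/0.9` rather than being 10 % of the pre-TEF
  expenditure — a small but principled distinction.

The balanced intake splits into three equal meals; meal calories split
50/20/30 % into carbohydrate/protein/fat and convert to grams with the
Atwater densities 4/4/9 kcal/g. Those are the `med` levels; `low` and
`high` are 0.8× and 1.5×. Diet bounds for the optimizer are the low/high
grams per macronutrient plus total-grams bounds at the same multipliers
of the med total, so the med diet is always interior and the feasible
set is never empty by construction.

## The synthetic surrogate

The real simulator is not redistributable, so training data come from a
small stochastic difference-equation system with the same contract.
Its design goals were: (i) the qualitative dynamics are right — γ reacts
within a week or two, β drifts slowly with the energy imbalance, τ is a
delayed, slowly resolving response with the largest noise; (ii) every
contract is testable at zero noise; (iii) the map from features to
trajectories is learnable but not trivial.

Per subject, with Δ the relative caloric imbalance of the diet
(share-weighted level multiplier minus 1):

* β(t) relaxes at rate 0.12/week toward an equilibrium
  `β₀·(1 + 0.3·Δ)` with weekly state noise (sd 0.1 kg/m²). At exact
  balance and zero noise β is constant; a surplus makes it strictly
  increasing.
* γ(t) is a fast first-order response (rate 0.7/week) to a target
  `82 + 0.08·(age−28) + 2.2·(β−22)₊ + 9·(carb multiplier − 1)` mg/dl,
  plus observation noise (sd 4 mg/dl).
* τ(t) tracks, at rate 0.45/week and with an explicit delay of
  `tau_lag` = 3 weeks, the target `15 + 1.5·(γ−88)₊ + 1.2·(β−22)₊` (au),
  plus the largest observation noise (sd 6 au). The delay-plus-filter
  reproduces the inflammatory inertia: a transient glucose peak produces
  a τ peak `tau_lag` weeks later with a slow decline.

The noise scales were chosen once, on physiological grounds: weekly
body-mass fluctuation of a few hundred grams, weekly fasting-glucose
variability of ~4–5 %, and cytokine variability of ~20–40 % CV —
cytokines have short lifespans relative to a weekly observation grid, so
τ must be the high-variability output both absolutely and relative to
its range. What the surrogate deliberately does **not** model: the
10-second internal resolution of the real simulator, hormone/fuel
dynamics, immune agent populations, and within-day meal timing.
Consequently, passing tests demonstrate that the pipeline recovers *this*
generator's structure at the stated sizes — they are evidence about the
machinery, not about the real simulator's biology.

## Bootstrap bands and coverage

Residuals are pooled per output across all (subject, week) cells and
resampled with replacement into B = 50 pseudo-trajectories
`y*_b(x,t) = ŷ(x,t) + e*_b(x,t)`; the band is the pointwise empirical
`q_α`/`q_{1−α}` envelope of the B pseudo-trajectories (inclusive
linear-interpolation quantiles, R type 7, so tests can be exact).
Replicate seeds derive deterministically from the master seed and the
replicate index. With all-zero residuals the band collapses onto the
prediction; bands at smaller α nest those at larger α.

A *refit* variant — re-train the emulator on each pseudo-response set
over the fixed design and read the band off the replicate predictions —
is available as `method = "refit"`. It is not the default for a reason
worth stating: the spread of refitted ensemble means estimates the
*estimation* uncertainty of the forest, not the predictive spread of a
trajectory, and such bands are several times narrower than the residual
scale (they covered ~30 % instead of ~90 % in our calibration
experiments). The pseudo-trajectory band is the construction whose
held-in coverage is close to nominal.

Two properties of the pooled construction deserve emphasis, because they
bound what coverage comparisons can show. For subjects in the training
design, each cell's own residual is exchangeable with the pool being
resampled, so mean held-in coverage sits near the nominal 1 − 2α for
*every* output regardless of its noise level (slightly below, ≈ 0.87 at
B = 50, because extreme quantiles of 50 draws are noisy). For held-out
subjects, coverage equals the nominal level minus a gap driven by how
much the test-residual distribution exceeds the training pool — a gap
that *shrinks* as iid noise grows, since noise (which the pool captures)
then dominates the structural generalization error (which it
understates). Outputs whose signal is hard to generalize relative to
their noise — β here, with its tiny weekly noise — are covered worst out
of sample; heavily noisy outputs approach calibration. Coverage
probability is reported as the fraction of the 26 weeks inside the band,
per output, averaged over subjects (`coverage_study`), alongside the
per-subject distribution.

## Evaluation design

Outputs are min–max scaled to [0, 1] using the *training* table only
(no leakage); test values outside the training range are flagged, never
clipped, so error measures stay honest. The per-week RMSE E(t) is
computed per output on the scaled values, making the three curves
comparable. The sample-size study repeats the whole pipeline — sample,
split 70/30, simulate, fit, evaluate, coverage — at training sizes
500/1000/1500/2000. These are a 10×-scaled version of the original
5000–20000 design; the full sizes run unchanged through the same code
when more time is available. The study's coverage statistic uses B = 20
replicates per size as its default bootstrap budget. A first/last-week
versus mid-horizon RMSE ratio (`edge_ratio`) is reported as a U-shape
diagnostic but deliberately not asserted in tests: whether errors
concentrate at the horizon edges depends on the generator.

## The diet optimizer

The inflammation-control problem minimizes the emulated squared load
Σ_t τ̂(t)² over the per-meal levels subject to the gram bounds. The
emulator's diet inputs are categorical with 27 combinations, so the
default algorithm is exhaustive enumeration — exact, instantaneous, and
trivially verifiable against an independent brute-force loop (which the
test suite does). Ties break by lowest total grams, then lexicographic
level order, making results deterministic. A continuous Nelder–Mead
mode over gram values (snapped to the nearest levels for emulator input)
exists for user-supplied gram-valued bounds; with the default bounds it
can only rediscover a level combination. Infeasible problems fail
loudly, naming the violated constraints.

## Numerical conventions and degenerate inputs

* All stage seeds derive from a single master seed through a string-hash
  (`derive_seed`), so every artifact is bit-reproducible and independent
  of evaluation order; per-subject simulation seeds make tables
  insensitive to row order.
* Quantiles are type 7; grid order is lexicographic in the canonical
  field order; encoded features are ordered numeric codes (ordinal
  levels carry real order information that one-hot coding would
  discard, and trees split ordinals natively).
* Degenerate inputs fail early with named errors: empty factor levels,
  constant output columns in scaling, B < 2 replicates, empty test
  tables, non-factorial grids passed to the stratified sampler.
* `fit_emulator` requires ≥ 1 tree and stores OOB errors from bagging;
  a constant-output table is fit exactly (useful as an arithmetic
  oracle in tests).

## Problem sizes used by the checks

The packaged checks run the study at training sizes 500–2000 with
B = 20, band calibration at k = 500 with B = 50, and the optimizer
oracle at 20 small random models; these sizes were chosen so the whole
suite completes in a few minutes on a single core while keeping ≥ 100
subjects behind every coverage average.

## Known limitations

* The surrogate is a stand-in: conclusions about the real simulator
  require retraining on its trajectories (the pipeline accepts any
  long-format CSV via `read_training_table`).
* Bands are pointwise, not simultaneous; a 90 % pointwise band does not
  contain 90 % of whole trajectories.
* Held-out coverage is not guaranteed near nominal — see the discussion
  above; an out-of-bag residual pool would narrow that gap and is a
  natural extension.
* The stratified sampler requires a full-factorial grid (always true
  for grids built by `enumerate_grid`); for arbitrary subject lists use
  `scheme = "random"`.
* Physical-activity variables are not optimized, only the diet; the
  objective is a single squared-load functional, not a multi-objective
  trade-off, and nothing here constitutes medical advice.
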