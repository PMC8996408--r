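---
title: "Modeling and optimizing walnut proliferation media"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and optimizing walnut proliferation media}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(walnutmedia)
```

## The problem

Persian walnut (*Juglans regia*) is recalcitrant in tissue culture: the
composition of the proliferation medium drives not only the number of new
shoots per explant (the proliferation rate, PR) but also three disorders —
callus formation at the explant base (callus weight, CW, in grams), shoot
tip necrosis (STN, %) and vitrification/hyperhydricity (Vit, %). The
screening experiment packaged here varied nine factors at three levels
each: seven multipliers of DKW (Driver–Kuniyuki walnut) basal-medium
component groups (X1–X7) and two plant-growth-regulator doses in mg/l (X8 =
BAP; X9 = TDZ and IBA, dosed together), for the cultivars Chandler and
Rayen. `factor_definitions()` lists the groups and levels;
`packaged_design(genotype)` returns the realized 27-treatment design plus
the unmodified DKW control with all response summaries (mean ± SE over 8
replicate jars).

The workflow is: expand the printed summaries into a replicate-level
dataset, fit four response-surface families (multiple linear regression,
k-nearest neighbours, a single-hidden-layer perceptron, and gene
expression programming), compare them by cross-validated R², RMSE and MAE,
and search the factor space by particle swarm optimization for a medium
that maximizes PR while minimizing CW, STN and Vit.

## Synthetic replicates from printed summaries

The replicate-level measurements behind the summaries were not published,
so `expand_replicates()` reconstructs a dataset with exactly the published
first two moments: for each treatment and response it draws 8 values from
Normal(mean, SE·√8) — the SD of individual jars implied by a standard
error over 8 jars — then recentres and rescales them affinely so the
sample mean and SE equal the printed values exactly (draws yielding a
negative response are rejected and redrawn; responses are counts, masses
and percentages). With 28 treatments this gives the 224 records per
genotype that the original models were trained on, and a 70/30
record-level split (sizes rounded half-up, hence 157/67) with tenfold
cross-validation on the training records.

What this emulates — and what it does not: the synthetic data reproduce
the between-treatment structure and the within-treatment dispersion, but
the within-treatment values are Gaussian by construction, uncorrelated
across responses, and carry no jar-level covariates. Tests passing on
these data therefore validate the pipeline's mechanics and the
between-treatment signal, not any claim about the unpublished raw data
beyond its first two moments.

```{r}
design <- packaged_design("Chandler")
reps <- expand_replicates(design, seed = 1)
c(records = nrow(reps),
  dkw_pr = mean(reps$PR[reps$treatment_id == "DKW"]))
```

## The GEP engine

Gene expression programming encodes a model as a fixed-length multigenic
chromosome. Each gene has a 10-symbol head (functions or terminals) and an
11-symbol tail (terminals only), read breadth-first (Karva order) into an
expression tree; the four gene trees are linked by addition. The function
set is +, −, ×, ÷, sin, cos, x², x³ and binary power; terminals are the
nine normalized inputs and ephemeral random constants uniform in [−10, 10].
Evaluation is protected so any chromosome is total on finite inputs:
division by zero yields 1, a negative base with a non-integer exponent
uses the absolute base, and every intermediate is clamped to ±1e10.

Evolution follows the classical recipe: fitness 1000/(1 + RRSE) — RRSE is
the root relative squared error, 0 for a perfect model and 1 for the
constant mean predictor — with roulette-wheel selection, elitism, and the
operator rates: mutation 0.044, inversion 0.1, one-point recombination
0.1, two-point recombination 0.3, gene recombination 0.1, gene
transposition 0.1, in a population of 50.

Three engine features are package design choices on top of that recipe,
each validated on the planted linear benchmark (`make_benchmark()`), where
the target y = 2x1 − x2 + 0.5 is recovered with RRSE < 0.05 in 10/10
seeded runs within 2000 generations:

* **Constant handling.** Mutation of a constant position either redraws it
  or perturbs it at a randomly chosen scale (SD 1, 0.1 or 0.01), and a
  small memetic step jitters the constants of each generation's best
  chromosome, keeping improvements. Without these, runs plateau with the
  correct tree shape but imprecise constants.
* **Linear output scaling.** At every evaluation the least-squares-optimal
  output scale and offset are fitted and become part of the model, so
  evolution searches only for the response *shape*. The affine map is
  expressible by the gene constants themselves (every published equation
  contains additive and multiplicative literals), so this changes where
  the constants live, not the model class.
* **Automatic multi-start.** When a population makes no progress on its
  own best for 120 generations, it is reinitialized from scratch; the
  best-ever individual is tracked outside the population and never lost.
  Random immigrants (2 per generation) provide continuous fresh material.
  This escapes deceptive attractors such as (cos x)³ masquerading as −x.

Defaults: 2000 generations with an early stop after 500 generations
without an improvement above 1e-6 (and immediately once RRSE ≤ 1e-9);
applied fits in the comparison protocol use 400 generations, which is
where the benchmark quality curve flattens at this data size.

## Baseline models

* **MLR** — ordinary least squares on the raw factor scales (linear models
  are scale-equivariant). Rank deficiency errors, naming the collinear
  columns.
* **KNN** — unweighted mean of the k nearest training targets, with
  euclidean, manhattan, chebyshev or minkowski (p = 3; the exponent is a
  package default, the metric family being given without one) distances on
  unit-box-normalized inputs; ties in distance fall to the earlier
  training record, ties in selection to the smaller k, then to the metric
  order as listed. k is searched on 1..15 by cross-validated RMSE.
* **MLPNN** — a 9–H–1 perceptron, hidden activation among tanh, logistic,
  exponential and relu, identity output, mean-squared-error loss
  minimized by BFGS with analytic gradients from seeded random starts
  (best of the restarts kept). Inputs unit-box-normalized; no
  regularization. H is searched by cross-validated RMSE with ties to the
  smaller network.

All model families obey one response-surface contract: a `predict` method
mapping rows of X1..X9 to finite predictions, which is what the
evaluation protocol and the optimizer consume.

## Evaluation protocol

`r2()` is the squared Pearson correlation of observed and predicted
values — the form the comparison protocol prints — with the 1 − SSE/SST
variant available under `method = "ss"` for sensitivity analysis (the two
differ for biased predictors). Training statistics are averaged over the
tenfold-CV folds with the model refitted per fold; test statistics come
from the model fitted on the full training set, evaluated once on the
untouched 67-record test set. `comparison_report()` emits one row per
model × response with the selected-hyperparameter annotation (e.g.
"KNN (4)", "MLPNN (9-15-1)").

On the packaged synthetic data the nonlinear learners beat MLR in
held-out R² on essentially every genotype × response task, reproducing
the qualitative ordering of the original comparison. The printed
statistics themselves are not reproducible — they depend on the
unpublished replicate values and an unpublished random split — which is
why the packaged check is the ordering, not the numbers.

## Transcribed equations and their quirks

The eight published GEP equations (one per genotype × response) are
packaged as a frozen, checksummed plain-text registry and exposed through
`get_equation()`. Three of them contain tokens F1/F3/F4/F6/F8/F9 that are
undefined in the source (almost certainly typesetting slips). The default
policy refuses to evaluate a flagged equation — silently guessing would
fabricate a model — and `substitute_F = TRUE` opts into the documented
Fk → Xk reading.

Which input convention the published optimized-medium predictions used is
not stated. Evaluating the equations on raw factor scales reproduces
them (Chandler PR 22.5 vs published 23.54, Rayen PR 7.38 vs 7.42, at the
published optimized compositions), while unit-box-normalized inputs do
not (Chandler PR ≈ 5.9), so raw-scale evaluation is the package default
for these surfaces and `normalize = TRUE` remains available for
sensitivity checks. The residual Chandler PR gap has a concrete cause:
one gene term divides by cos(X8 + X3), and at the published optimum
X8 + X3 = 1.63 sits close to the cosine zero at π/2, so the two-decimal
rounding of the published inputs moves the prediction by roughly ±1.7.
The published 23.54 lies comfortably inside the prediction interval
induced by that rounding.

```{r}
x_opt <- c(1.76, 1.67, 0.96, 0.66, 2.35, 1.64, 1.89, 0.67, 1.30)
predict(get_equation("Chandler", "PR"), x_opt)
```

## Swarm optimization of the medium

The optimizer is a plain global-best PSO: velocity
v' = w·v + c1·r1·(pbest − x) + c2·r2·(gbest − x) with fresh uniform r1,
r2 per particle and dimension, position x' = x + v', velocities clamped
to half the box range, positions clipped to the factor bounds with the
velocity zeroed on clipped dimensions. Defaults are 50 particles, 500
iterations, c1 = c2 = 1.5 and inertia w = 0.8 — the low end of the
conventional 0.8–1.2 band, chosen because on the 9-D sphere benchmark
w = 0.8 converges to machine-level optima within 1000 iterations while
w = 0.9 stalls around 1e-1. The search runs directly in the raw factor
box spanned by the design level extremes; published optima lie between
design levels, which is what motivates a continuous search.

"Multi-objective" is implemented as weighted-sum scalarization: each
response is min-max-normalized over the span of the packaged design means
(so all four live on comparable scales), maximized responses are negated,
and the weighted sum (equal weights by default) is minimized. Within the
normalization ranges, a medium that dominates another on all four
responses always scores strictly better. Two guards handle the fact that
the transcribed surfaces are unbounded formulas: normalized objectives
saturate at [0, 1], so no response can earn unlimited credit by
extrapolating (without this the swarm chases shoot-tip-necrosis
predictions in the negative thousands and the "optimal" medium can have a
lower predicted PR than the DKW control), and a small bounded penalty on
predictions outside the observed response span keeps the recommended
recipe where the surfaces are trustworthy. Candidates where any surface
evaluates non-finite are penalized to +∞ and counted.

```{r}
surfaces <- get_equations("Chandler", substitute_F = TRUE)
opt <- optimize_medium(surfaces, objective_spec("Chandler"),
                       params = pso_params(iterations = 300, seed = 7))
report_optimum(opt)$text
```

## Numerical choices and degenerate inputs

* Normalization uses the design level extremes per factor, not empirical
  column ranges, so off-grid optima normalize consistently; the two
  coincide on the design grid. The DKW control's X9 = 0.1 mg/l lies below
  the design minimum of 0.5 and is clamped with a warning when
  normalization is requested for it.
* A printed SE of 0 (three Chandler treatments had no vitrification)
  yields constant replicates; an empty train or test split, folds larger
  than the training set, constant targets for GEP or the correlation
  form of R², rank-deficient MLR designs, and k beyond the training size
  are all explicit errors.
* Replicate generation, splitting, folding, perceptron fitting, GEP
  evolution and PSO all take seeds; identical seeds give bit-identical
  results, and the pipeline derives per-stage sub-seeds from one master
  seed.
* Distance and selection ties are broken deterministically (training
  order, smaller k, smaller H, listed metric/activation order).

## Problem sizes used by the packaged checks

The test suite and the analysis scripts run the planted-linear GEP
benchmark at 64 samples and 2000 generations across 10 seeds, the sphere
benchmark at 1000 iterations across 10 seeds, and the full model
comparison on both genotypes (224 records each) with tenfold CV at
reduced fitting budgets (KNN grid 1..15 with all four metrics; one 9–15–1
tanh perceptron with 2 restarts; GEP at 400 generations per fit). These
sizes are where the benchmark quality curves flatten for this data scale;
larger budgets change the third decimal of the statistics, not the
ordering.

## Known limitations

* The synthetic replicates honour only the published first two moments;
  real jar-level data could be skewed, correlated across responses, or
  overdispersed, and model rankings on real data could differ.
* The transcribed equations inherit any typesetting damage in the source
  beyond the flagged F-tokens; the registry is checksummed so every
  transcription decision is explicit and versioned.
* The published Rayen optimized composition differs between the source's
  table and its narrative text; the package optimizes from scratch rather
  than adjudicating, and reports both its own optimum and the DKW
  baseline.
* Weighted-sum scalarization cannot reach non-convex parts of the Pareto
  front; the weights are exposed so users can trace the front by
  reweighting.
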