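# walnutmedia

Machine-learning response surfaces and swarm optimization for Persian
walnut (*Juglans regia*) in vitro proliferation media.

Formulating a proliferation medium for walnut means balancing four
responses at once: the proliferation rate (PR, new shoots per explant)
should be high, while callus weight (CW, g), shoot tip necrosis (STN, %)
and vitrification (Vit, %) should be low. This package is for tissue-culture
researchers and modellers who want that balancing act as a reproducible
computation rather than bench trial and error. It ships:

* the realized 9-factor, 3-level screening design — 27 treatments plus the
  DKW (Driver–Kuniyuki walnut) control — with per-treatment response
  summaries (mean ± SE over 8 replicate jars) for the cultivars Chandler
  and Rayen, plus a generic L27 orthogonal-array generator;
* a moment-matched synthetic-replicate generator: per treatment and
  response, 8 draws from Normal(mean, SE·√8) affinely adjusted so the
  sample mean and SE equal the published values exactly (224 records per
  genotype), with a seeded 70/30 split (157/67) and tenfold CV;
* four response-surface families under one `predict()` contract —
  multiple linear regression, k-nearest neighbours (four distance
  metrics), a single-hidden-layer perceptron trained by BFGS, and a
  from-scratch gene expression programming (GEP) engine: multigenic Karva
  chromosomes (head 10, four genes linked by addition), protected
  evaluation, fitness 1000/(1 + RRSE), roulette selection with elitism,
  and the operator rates mutation 0.044 / inversion 0.1 / one-point 0.1 /
  two-point 0.3 / gene recombination 0.1 / gene transposition 0.1;
* model comparison by R² (squared Pearson correlation), RMSE and MAE,
  as tenfold-CV training averages plus held-out test statistics;
* the eight published GEP equations as a frozen, checksummed registry of
  evaluable surfaces; and
* a bound-constrained particle swarm optimizer
  (vᵢ₊₁ = w·vᵢ + c₁r₁(pbest − xᵢ) + c₂r₂(gbest − xᵢ); xᵢ₊₁ = xᵢ + vᵢ₊₁)
  that minimizes a weighted sum of min-max-normalized objectives (PR
  negated) over the factor box and reports the optimized recipe against
  the DKW baseline.

## Worked example

```r
library(walnutmedia)

design <- packaged_design("Chandler")
reps   <- expand_replicates(design, seed = 1)   # 224 records
sp     <- split_train_test(reps, seed = 2)      # 157 train / 67 test

Xn <- normalize_factors(as.matrix(sp$train[paste0("X", 1:9)]), clamp = TRUE)
gep <- evolve_gep(Xn, sp$train$PR,
                  gep_config(generations = 400, stall_generations = 400),
                  seed = 42)
gep$rrse
#> [1] 0.5875677

Xte <- normalize_factors(as.matrix(sp$test[paste0("X", 1:9)]), clamp = TRUE)
r2(sp$test$PR, predict(gep, Xte))
#> [1] 0.4845487
```

The training RRSE of 0.59 says the evolved formula explains about
1 − 0.59² ≈ 65% of the training variance; the held-out R² of 0.48 is the
squared correlation between observed and predicted proliferation rates on
the 67 untouched test records.

Optimizing the published Chandler surfaces:

```r
surfaces <- get_equations("Chandler", substitute_F = TRUE)
opt <- optimize_medium(surfaces, objective_spec("Chandler"),
                       params = pso_params(iterations = 300, seed = 7))
cat(report_optimum(opt)$text, sep = "\n")
#> Optimized medium:
#>   0.69 x NH4NO3, CaNO3, ZnNO3
#>   1.96 x KNO3
#>   2 x K2SO4
#>   2.5 x MgSO4, MnSO4, CuSO4
#>   2.5 x KH2PO4, H3BO3, Na2MoO4
#>   2 x FeEDDHA
#>   2 x Thiamine, Nicotinic acid, Glycine
#>   1.05 mg/l BAP
#>   0.53 mg/l TDZ, IBA
#>   predicted: PR 19.14, CW 0.09 g, STN 10.72, Vit 2.00
#> DKW control predicted: PR 10.47, CW -2.02 g, STN 14.25, Vit 2.55
```

The optimized medium nearly triples the predicted shoot yield of the DKW
control while holding callus, necrosis and vitrification at the low end
of the observed range. (The negative control CW is the transcribed
surface itself misbehaving at the control composition — these are
unconstrained formulas with no non-negativity guarantee, which is one
reason the optimizer's objective saturates outside the observed response
span.)

The numbered scripts under `analysis/` run the whole study end to end
(simulate → fit → evaluate → optimize), writing CSV/JSON artifacts under
`results/`.

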