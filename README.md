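# ilqspr

QSPR modelling of gas–ionic-liquid partition coefficients (log K) from
2D molecular descriptors of the ionic liquid's cation.

## The problem

With the anion held fixed (e.g. [Tf2N]⁻), how strongly a volatile
solute partitions from the gas phase into an ionic liquid — log₁₀ of
the liquid/gas concentration ratio at 298 K — is a property of the
cation, and can be regressed on numeric descriptors of the cation's 2D
structure. The data regime is wide and short: ~57–60 cations against
~10²–10³ candidate descriptors after pruning. `ilqspr` implements the
complete workflow for that regime, for anyone building or auditing
sparse QSPR models on small series:

- **Preparation** — descriptor pruning (missing / constant / collinear
  at |r| ≥ 0.95, first-in-order kept), standardization with stored
  statistics, and the deterministic sorted "every tenth observation"
  10-fold partition.
- **MLR** — ordinary least squares (ŷ = β₀ + β₁X₁ + … + β_kX_k, β̂ =
  (XᵀX)⁻¹Xᵀy) with descriptor selection by orthogonal matching pursuit
  plus an *expulsion search*: the descriptor most correlated with log K
  is repeatedly expelled from the pool and OMP rerun until max |r| <
  0.4, the best candidate by cross-validated r² winning.
- **SVR** — ε-insensitive support vector regression with RBF kernel
  (ŷ = Σ_{i∈SV} αᵢ K(xᵢ, x) + b), greedy forward selection with
  substitution passes, and exhaustive grid tuning of (C, ε, γ).
- **GPR** — Gaussian process regression with the composite kernel
  σ₀² + x·x′ + RBF(ℓ) + white noise, hyperparameters by multi-start
  marginal-likelihood maximization; predictive mean and covariance
  f̄\* = K(X\*,X) K(X,X)⁻¹ y,
  V[f\*] = K(X\*,X\*) − K(X\*,X) K(X,X)⁻¹ K(X,X\*).
- **Model size** — all families share the 20% rule: k+1 descriptors are
  kept only while (err_k − err_{k+1})/err_k ≥ 0.20 with err = 1 − r²cv.
- **Evaluation** — per-fold and aggregate r², RMSE and Lin's
  concordance correlation coefficient; permutation importance.
- **Diagnostics** — leverage (h\*₃ = 3(k+1)/n), internally studentized
  residuals, Cook's distance Dᵢ = rᵢ²/(k+1) · hᵢᵢ/(1−hᵢᵢ), and the
  influence report behind applicability-domain plots.
- **Synthetic data** — a seeded generator planting sparse (non)linear
  signals in block-correlated descriptor matrices, with collinear and
  constant decoys and injectable anomalies, so every stage is testable
  without external data.

## Worked example

Build a linear model on planted synthetic data (four true descriptors
among 200, population r² 0.9), exactly as the pipeline would on a real
series:

```r
library(ilqspr)

d     <- makePlantedLinear(syntheticSpec(seed = 11))
dm    <- standardizeDescriptors(pruneDescriptors(d$X))
y     <- unname(d$y)
X     <- as.matrix(dm)
folds <- assignFolds(y, 10)

sel <- selectMlr(X, y, folds, kMax = 5)
sel$model
#> LinearModel: 4 descriptors, n = 60
#> (Intercept)        D001        D006        D011        D016
#>      1.2273      1.1392     -0.8765      0.5089     -0.4203

crossValidate(mlrSpec(descriptorNames(sel$model)), X, y, folds)
#> FoldStats (10 folds): train r2 0.924 rmse 0.466 ccc 0.960 | test r2 0.901 rmse 0.481 ccc 0.947

permutationImportance(sel$model, X[, descriptorNames(sel$model)], y,
                      seed = 11)
#> ImportanceTable (30 repeats, seed 11):
#>   descriptor importance     sd
#> 1       D001      0.916 0.1210
#> 2       D006      0.544 0.0774
#> 3       D011      0.172 0.0343
#> 4       D016      0.116 0.0214

influenceTable(sel$model, X[, descriptorNames(sel$model)], y)
#> InfluenceTable: n=60, k=4, h*3=0.2500; high leverage 0, |r|>2 1, D>1 0

d$truth$signal
#> [1] "D001" "D006" "D011" "D016"
```

The selection recovered exactly the four planted descriptors
(standardized coefficients close to the planted (1, −0.8, 0.6, −0.5)),
the fold-averaged test r² of 0.901 sits at the generator's calibration
target, permutation importance ranks the descriptors by |β|, and the
influence table shows a clean fit (no high-leverage cations, one
moderate residual, no Cook's distance above 1).

The same flow runs end-to-end from files with
`runPipeline(pipelineConfig(...))`, which writes model / fold-statistics
/ importance JSON artifacts, influence CSVs and a log, all stamped with
a config hash and seed. A thin CLI lives in
`inst/scripts/run_pipeline.R`.

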