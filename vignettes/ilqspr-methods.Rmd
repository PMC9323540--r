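---
title: "Modelling gas–ionic-liquid partition coefficients with ilqspr"
author: "ilqspr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling gas-ionic-liquid partition coefficients with ilqspr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ilqspr)
```

## The modelling problem

Ionic liquids (ILs) are organic salts that are liquid near room
temperature. How strongly a volatile solute (hexane, cyclohexane,
benzene, ...) partitions from the gas phase into an IL is summarized by
the partition coefficient K — the ratio of the solute's equilibrium
concentration in the liquid to its concentration in the gas — reported
as log10 K at 298 K. When the anion is held fixed (here the common
bis(trifluoromethylsulfonyl)imide anion, [Tf2N]–), log K becomes a
property of the cation alone, and a quantitative structure–property
relationship (QSPR) can be built from numeric descriptors of the
cation's 2D molecular graph.

The setting is extremely wide and short: a series holds roughly 57–60
cations, while a 2D descriptor engine produces on the order of 1600
candidate descriptors. Everything in this package is shaped by that
imbalance — aggressive descriptor pruning, sparse model building (3–5
descriptors), 10-fold cross-validation as the selection currency, and
influence diagnostics to see which cations the final linear model leans
on.

## Data preparation

`pruneDescriptors()` removes, in order and with a per-column log:
columns containing missing values (descriptor-engine failures are
recorded as NA by `computeDescriptors()`), zero-variance columns, and —
scanning columns in their input order — any later column whose absolute
Pearson correlation with an already-retained column reaches the
threshold (default |r| ≥ 0.95). The first column of a collinear set
survives, which makes the rule reproducible without randomness. The
threshold is exposed because no single value is canonical; 0.95 is a
common choice that removes near-duplicates (lagged autocorrelation
descriptors, rescaled counts) without touching merely related
descriptors. Dropping the *column* on missing values, rather than the
row, protects the small n.

`standardizeDescriptors()` centers and scales each surviving column to
mean 0, sample sd 1, using full-series statistics computed once before
any fold splitting; the means and sds are stored so a fitted model can
be applied to new cations (`applyStandardization()`). Computing the
statistics before fold splitting leaks a small amount of information
into the held-out folds. That mirrors the workflow this package
implements, and the leakage is documented rather than silently "fixed":
with n ≈ 60 and 10 folds the effect on column statistics is at the
percent level, and it applies identically to every candidate model, so
model ranking is essentially unaffected.

`assignFolds()` sorts observations by ascending log K (ties broken by
input order, so the procedure is deterministic and seedless) and deals
them round-robin into folds: the observation of zero-based rank j goes
to fold (j mod 10) + 1. Every fold then spans the whole response range
("every tenth cation"), which matters when the response range is narrow
and the models are judged by per-fold r².

## The three model families

**MLR.** `fitOls()` is ordinary least squares on an intercept plus the
selected standardized descriptors (QR decomposition; rank deficiency is
an error, not a silent drop). On standardized descriptors the intercept
equals mean(y), and standardized coefficients are directly comparable as
importance measures.

Descriptor selection uses orthogonal matching pursuit (`ompSelect()`):
starting from the intercept-only residual, repeatedly add the descriptor
with the largest absolute Pearson correlation to the current residual
and refit OLS on the active set (classical OMP with refitting, not plain
matching pursuit). OMP alone anchors on whatever single descriptor
correlates best with log K, so `expulsionSearch()` widens the search: it
runs OMP, then expels the descriptor most correlated with log K from the
selection pool and reruns OMP, repeating until the largest remaining
|correlation| drops below 0.4. Each round's candidate is scored by
cross-validated test r² and the best candidate wins (ties to the
earliest round). Expelled descriptors leave only the *pool*; a candidate
is always evaluated with its own descriptors. We stop as soon as the
correlation condition is met, without one extra OMP pass — the condition
is a stopping rule, not a final iteration trigger.

**SVR.** `fitSvr()` fits ε-insensitive support vector regression with
the squared-exponential kernel K(x, x′) = exp(−γ‖x − x′‖²). The dual is
solved by the libsvm SMO solver (package e1071) at a tightened
convergence tolerance; the fitted object exposes the signed dual
coefficients (|αᵢ| ≤ C), support indices and intercept, and the test
suite checks the duals against an independent generic-QP solution. The
γ tokens follow the common convention: "auto" is 1/p and "scale" is
1/(p · Var(X)) with the population variance of all matrix entries.
`tuneSvr()` evaluates an exhaustive grid (defaults: C ∈ {0.001, 0.005,
0.1, 0.5, 1, 5, 10, 50, 100, 500, 1000}, ε ∈ {0.001 ... 10}, γ ∈
{0.001 ... 0.1, "auto", "scale"}) by fold-averaged cross-validated r²,
ties to the earlier grid point. The C axis deliberately contains both 1
and 5 as separate values.

**GPR.** `fitGpr()` implements Gaussian process regression with the
composite kernel sigma0² + x·x′ + exp(−‖x − x′‖²/(2ℓ²)), plus white
noise of variance noiseLevel on the training diagonal. The three
hyperparameters maximize the log marginal likelihood by L-BFGS-B in log
space, from the user's initialization plus 5 seeded log-uniform
restarts; the best start wins, so the optimized marginal likelihood can
never fall below its initial value. Cholesky factorization uses jitter
escalation 1e-10 → 1e-6 (tenfold steps) and fails loudly with a
conditioning report beyond that. Predictions follow the standard
posterior mean/covariance identities, with the white-noise term included
only between identical training indices — so the predictive variance
refers to the latent function. No established R package fits exactly
this kernel family with marginal-likelihood optimization, which is why
the implementation is in-package; its posterior is verified against
explicit matrix algebra in the tests.

**Shared selection for the kernel models.**
`greedySubstitutionSelect()` grows the descriptor set bottom-up by
cross-validated r²: each forward addition is followed by substitution
passes in which every selected position is tried against every pool
replacement and the single best strictly-improving swap is adopted,
until no swap improves. Positions are scanned in selection order; one
swap per pass keeps the procedure deterministic where several swaps
would tie. During selection the SVR hyperparameters are held at
defaults (C = 1, ε = 0.001, γ = "auto"); the grid tuning runs once on
the concluded set. Scores are memoized, so the scorer must be
deterministic — the GPR scorer therefore carries a fixed restart seed.

**Model size.** All three families share the same stopping rule
(`chooseModelSize()`): starting from one descriptor, a model with one
more descriptor is kept only while it corrects at least 20% of the
previous prediction error, with error measured as 1 − r²(cv):
accept k+1 iff (err_k − err_{k+1})/err_k ≥ 0.20. The rule is strictly
sequential — a large improvement at k+2 cannot rescue a failed step at
k+1. The boundary case (exactly 20%) is accepted. We use
cross-validated r² in the rule for all three families for uniformity;
a training-r² variant of the candidate criterion is exposed via
`expulsionSearch(criterion = "train")`.

## Evaluation

`crossValidate()` refits the model spec on each fold's complement and
scores r², RMSE and Lin's concordance correlation coefficient (CCC) on
both the training portion and the held-out fold. CCC,
2·cov(y, ŷ) / (var(y) + var(ŷ) + (mean(y) − mean(ŷ))²), penalizes both
imprecision and bias against the identity line; both moments use the
n-denominator convention, which keeps the statistic scale-consistent.
Two aggregations are reported because "statistics on all folds" is
ambiguous: the unweighted mean of per-fold statistics (the primary
report) and the statistics of the pooled out-of-fold predictions (the
`pooled` slot). A null model can produce constant predictions, for
which CCC is undefined; the harness records NA there rather than
failing.

`permutationImportance()` measures, for a fitted model without
refitting, the mean decrease in r² when one column is permuted
(default 30 repeats). Values above 1 are expected for dominant
descriptors: permuting them drives r² negative. Each column's
permutations are drawn from a seed derived from the column's *name*,
so a descriptor's importance is invariant to relabeling or reordering
of the other columns.

## Influence diagnostics and applicability domain

For linear models only, `influenceTable()` combines leverage (the hat
matrix diagonal of the design with a constant column), internally
studentized residuals and Cook's distance
Dᵢ = rᵢ²/(k+1) · hᵢᵢ/(1−hᵢᵢ). Flags follow the conventional
thresholds: high leverage above 3(k+1)/n, moderate above 2(k+1)/n
(the moderate threshold is a convention supplied by this package, with
the factor configurable), |r| > 2 worth inspection, |r| > 3 a likely
outlier, D > 1 influential. Two sign/formula conventions deserve note:
the standardized residual is (ŷᵢ − yᵢ)/(σ̂√(1−hᵢᵢ)), so a positive
value is an overprediction; and the raw residual is defined as
eᵢ = yᵢ − ŷᵢ, the only definition consistent with σ̂² = eᵀe/(n−k−1) —
a formula stating eᵢ = (1−hᵢᵢ)·yᵢ describes the deleted-residual
numerator and is not used here. Residuals are internally (not
externally) studentized, matching the single global σ̂. A numerically
perfect fit reports all-zero standardized residuals instead of 0/0;
an observation with hᵢᵢ = 1 is flagged undefined instead of infinite.

## The synthetic generator

`makePlantedLinear()` draws a block-correlated descriptor matrix
(standard-normal marginals; within-block correlation ρ = 0.3 in blocks
of 5 columns), plants a sparse signal — one descriptor in each of the
first kTrue blocks, standardized coefficients (1, −0.8, 0.6, −0.5) —
and adds Gaussian noise calibrated in closed form so the population r²
of the true model equals its target (default 0.9): because the signal
columns sit in distinct blocks, Var(signal) = Σβ², and
σ² = Var(signal)·(1−r²)/r². Closed-form calibration keeps generation
O(np) and exactly seeded; `targetR2 = 1` is allowed as the noiseless
limit. Collinear decoys are appended with *exact* sample correlation
0.995 to signal columns (constructed by orthogonalization, not by
adding noise and hoping), plus constant decoys — both exist so the
pruning stage has something real to find. Defaults (n = 60, p = 200
base descriptors) emulate the shape of a cation series: tens of
observations, hundreds of surviving descriptors, a sparse
interpretable signal, cv r² near 0.9, log-K-scale intercept 1.2.

`makePlantedNonlinear()` adds amplitude·(x₁x₂ + 0.5(x₁² − 1)) on the
first two signal descriptors; the term has zero covariance with the
linear part (odd/even moment orthogonality) and variance 1.5·amplitude²,
so the same closed-form noise calibration applies. It exists to give
the kernel models something a linear model provably cannot fit.
`injectAnomalies()` appends high-leverage rows (signal descriptors at
4 sd, response consistent with the true model) and high-residual rows
(a typical profile with the response shifted by 5 noise sd) for the
diagnostics fixtures.

What the generator does *not* emulate: real descriptor distributions
(counts, zero-inflated Chi indices, heavy tails), structured
descriptor families with graded correlations, measurement error in
log K, and of course chemistry — there are no SMILES behind the
columns. Passing tests on planted data therefore demonstrate that the
algorithms do what they claim under known ground truth, not that any
particular chemical series is predictable.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full pipeline at the
study-like sizes (n = 60, p = 150–200, 10 folds; 50 replicates for the
recovery rates, 20 for the anomaly-detection rates) and smaller toys
for the algebraic oracles; these sizes were chosen as the smallest at
which the statistical claims are meaningful. Other numerical choices:
Pearson correlation throughout the selection rules; OMP stops early
with a warning if the residual becomes numerically zero; rank-deficient
designs are errors naming the dependent columns; ties in fold sorting
break by input order, ties in candidate scoring by earliest round or
grid order; the SVR solver runs at tolerance 1e-6 so its duals are
comparable to a high-precision QP solution.

## Known limitations

- The reported cross-validation statistics inherit the mild leakage of
  full-series standardization and of selecting descriptors on the same
  folds used for reporting; with n ≈ 60 a fully nested protocol would
  be noisy, but the numbers should be read as optimistic by a small
  margin.
- The expulsion search scores one candidate per pool state; it does
  not enumerate all size-k subsets and can miss optima that exhaustive
  search (used as the test oracle at p ≤ 8) would find.
- The 20% size rule is sequential and can stop early when the second
  descriptor's marginal gain is just under threshold even though later
  descriptors would help — visible occasionally with SVR under the
  default selection hyperparameters.
- GPR marginal-likelihood surfaces are multimodal; 5 restarts are a
  pragmatic default, not a guarantee of the global optimum.
- Influence diagnostics apply to the linear models only; there is no
  analogous applicability-domain measure for the SVR/GPR fits here.
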