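---
title: "Longitudinal enrichment of imaging-genetic cohorts: model, solver and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal enrichment of imaging-genetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longenrich)
```

## The problem

Longitudinal neuroimaging cohorts rarely deliver the same number of scans
per participant: visits are missed, participants drop out, acquisitions are
discarded during quality control. Most prediction pipelines respond by
truncating everyone to the common visit count or by imputing the missing
scans; both discard or fabricate information. `longenrich` instead learns,
for each participant `i`, a projection matrix `W_i` (d features x r1) that
compresses the participant's most recent scan `x_i` into a fixed-length
"enriched" vector `z_i = t(W_i) x_i`. The histories (all earlier visits,
however many there are) shape `W_i`; the enriched vectors have the same
length for everyone and can feed any conventional regression model.

The projections are not learned in isolation. Three additional sources of
signal constrain them:

* a static SNP matrix `X_SNP` factorized as `H0 G0`, with a group-sparsity
  penalty on `H0` organized by linkage-disequilibrium (or gene) groups, so
  whole groups of SNP loadings are switched on or off together;
* clinical scores for the labeled (training) subset, tied in through an
  estimated score matrix `F = [F_l | F_u]` with the hard constraint
  `F_l = Y_l` and a regression factor `F ~ t(U) G1`;
* a shared latent representation per participant: the enriched matrix `Z`
  is factorized as `H1 G1` and aligned with the genetic factor (`G1 ~ G0`),
  so all three views are explained by one low-dimensional participant
  embedding.

## The objective

Writing `Z = [t(W_1) x_1, ..., t(W_n) x_n]`, the fitted criterion is

```
||F - t(U) G1||_{2,1}
  + g1 * sum_i ||X_i - W_i t(W_i) X_i||_{2,1}
  + g2 * ||Z - H1 G1||_{2,1}
  + g3 * ||X_SNP - H0 G0||_{2,1}
  + g4 * ||G1 - G0||_{2,1}
  + g5 * sum_k ||H0^k||_F
  + g6 * (||W_(1)||_* + ||W_(2)||_*)
  + g7 * ||U||_1
subject to  F_l = Y_l,  t(W_i) W_i = I.
```

Every data-fit term uses the row-wise L2,1 norm (sum of row Euclidean
norms), which caps the influence of any single outlying row. `W_(1)`
(horizontal concatenation of the `W_i`) and `W_(2)` (concatenation of their
transposes) are the two unfoldings of the projection stack; penalizing
their trace norms couples all participants' projections toward a shared
low-rank structure — mode 1 pulls the column *spans* together, mode 2
aligns the *bases* across participants.

Two conventions deserve a note because the norms involved are written
ambiguously in parts of the literature this model descends from:

* The L2,1 norm here is a sum over **rows**, matching the definition used
  to build the reweighting matrices (each weight indexes `e_j^T(...)`, a
  row). Sample-wise robustness would group by columns; we implement the
  row form exactly and expose the weight matrices so the solver is
  agnostic to the choice.
* The group penalty on `H0` is the sum of per-group **Frobenius** norms
  (the form implied by its block-diagonal reweighting matrix), not the sum
  of per-group L2,1 norms that a group-robust reading would suggest. The
  reweighted form is what the solver minimizes, so it is authoritative
  here.

## The solver

The objective is non-smooth; the solver uses iterative reweighting (IRLS).
Each non-smooth term is majorized by a weighted quadratic whose weights are
computed from the current iterate — `1 / (2 sqrt(||r_j||^2 + delta))` for a
residual row `r_j`, one scalar per SNP group for the group penalty, and
`0.5 (W W' + delta I)^(-1/2)` for each trace norm. `delta` (default `1e-8`)
smooths the weights so they stay finite at zero residuals; all closed forms
use the smoothed expressions, never raw inverses.

The smoothed surrogate is minimized by ADMM. Copies `A = U` and
`B_i = W_i` decouple the L1 term from the regression factor and the
quartic PCA term from the orthogonality constraint; four multiplier
families enforce `F_l = Y_l`, `t(W_i) W_i = I`, `A = U`, `B_i = W_i`, with
penalties grown geometrically (`rho1 = rho2 = 1.05`,
`rho3 = rho4 = 1.15` per sweep, capped at `mu_max = 1e8`). One sweep
updates `F, U, A, H1, G1, H0, G0`, then `W_i, B_i` per participant, then
the multipliers. Every block update is the exact stationary point of the
augmented Lagrangian restricted to that block:

* `U` and `F` are closed forms; `A` solves a diagonal system per column
  (the L1 reweighting differs per column of `U`).
* `H1`, `G1`, `G0` solve single linear systems.
* `H0` couples a diagonal row weight on the left with `G0 G0'` on the
  right; after normalizing by the row weights it is a Sylvester equation,
  solved by `solve_sylvester()` (eigendecomposition of the small factor).
* Each column of `W_i` solves a shifted `d x d` system: the imaging
  weight matrix is diagonal, so columns couple only through a rank-one
  term `x_i x_i'`. This step dominates the per-iteration cost, which grows
  as `n * r1 * d^2 * (d + r1)`.

### Numerical safeguards (and why they exist)

The split objective is *bilinear* in several block pairs (the label term in
`(A, U)`, the PCA term in `(W_i, B_i)`), so an individual block subproblem
can be indefinite while the penalties are still small. Solving such a
system lands on a saddle and can send the iterate off to infinity — we
observed exactly this on cohorts whose histories are low-rank. Two
safeguards make the sweep robust:

* **Proximal convexification.** Before solving a block system we check its
  smallest eigenvalue; if it is below a floor we add `tau * I` to the
  system and `tau * current` to the right-hand side, i.e. we minimize the
  subproblem plus `(tau/2) ||block - current||^2`. The shift is scaled
  with the negative curvature so the proximal step stays on the order of
  the current block. When the subproblem is already positive definite,
  `tau = 0` and the update is the exact stationary point (this is the case
  the contract tests exercise).
* **Matched weight refresh (interleaved mode, the default).** The PCA
  weights of participant `i` are re-evaluated at the residual of whichever
  copy enters the subproblem being solved. This bounds every weighted
  residual row by 1/2 regardless of how small the raw residual is. With
  weights frozen for a whole inner loop (`interleaved = FALSE`, available
  for study), a participant whose history is exactly rank-`r1` starts at
  zero residual, gets weight `1/(2 sqrt(delta))`, and the first drift of
  `W_i` turns the weighted term into an enormous indefinite form: the
  nested scheme is faithful to a strict reading of the algorithm but
  unstable, which is why interleaving is the default.

The outer loop re-evaluates the true objective after every inner loop —
at the *feasible representative* of the iterate (each `W_i` polar-projected
onto the orthonormal manifold, `F_l` clamped to `Y_l`): the constrained
objective is only defined on the constraint set, and an infeasible iterate
under-counts it, which would make early "progress" an artifact of loose
constraints. The
inner solve is inexact, so a weight refresh near a fixed point can tick
the objective up by a hair; in that event the solver retries from the best
iterate with the grown (stiffer) penalties rather than recording an ascent
step. Convergence is declared when the relative objective change falls
below `tol_obj` *and* all four constraint residuals are below
`tol_residual`.

### Initialization

The factor matrices start at small seeded random values, `G0 = G1` at a
row-orthonormalized random sketch of the initial enriched matrix, `F_l` at
the known labels, and `F_u` at zero. Each `W_i` starts at the top-`r1`
left singular basis of the participant's history — with two refinements
that experience forced on us:

* **Pooled completion.** When a history has fewer than `r1` visits its
  singular basis is rank deficient. Random orthonormal padding makes the
  extra enriched coordinates pure noise; we instead complete with the
  cohort-level principal directions (orthogonalized against the personal
  span), which are exactly the directions the trace-norm coupling favors.
* **Procrustes alignment.** A singular basis is unique only up to column
  sign (and rotation in degenerate blocks), yet `z_i = t(W_i) x_i` is only
  comparable across participants if every basis resolves that ambiguity
  the same way. Each `W_i` is therefore rotated, within its own span, onto
  the pooled principal directions. Without this the enriched coordinates
  of different participants live in arbitrarily rotated frames and carry
  no cross-participant meaning; with the geometric penalty growth the
  solver cannot escape such a start, so the initialization must already be
  consistent.

Why initialization matters so much here: the penalty parameters grow
geometrically with every inner sweep, so after a few dozen sweeps the
copies `B_i` pin the projections down. The solver refines but does not
fundamentally restructure its starting point. This mirrors the published
algorithm (same growth factors) and is why both refinements above are
deterministic functions of the data rather than tunable knobs.

### Preprocessing

Imaging features (histories pooled with last records) and SNP rows are
z-scored by default (`standardize = TRUE`); the scaling is recorded in the
fit object. The model's terms compare residual rows across features, which
is only meaningful on a common scale. Clinical scores are never scaled.

## Hyperparameters

| parameter | default | meaning |
|---|---|---|
| `gamma1` | 0.1 | robust per-participant PCA fit |
| `gamma2` | 1e-4 | enriched-imaging factorization |
| `gamma3` | 1e-2 | SNP factorization |
| `gamma4` | 1e-3 | alignment of latent factors |
| `gamma5` | 0.1 | SNP group sparsity |
| `gamma6` | 0.1 | trace-norm coupling of projections |
| `gamma7` | 0.1 | L1 sparsity of regression weights |
| `r1` | 5 | enriched imaging dimension |
| `r2` | 3 | shared latent dimension |
| `delta` | 1e-8 | weight smoothing |
| `rho1..rho4` | 1.05/1.05/1.15/1.15 | penalty growth per sweep |
| `mu1..mu4` init | 1 | initial penalties |

The gamma defaults are the values tuned on the ADNI cohort in the source
study; the iteration controls, `mu` initializations, `delta` and `mu_max`
are this package's choices (the published account does not specify them).
Initial penalties should be on the order of the data-term curvature: for
the standardized multi-term model at the default gammas, 1.0 works; for a
pure PCA limit (`gamma1 = 1`, everything else 0) the curvature is
`||X_i X_i'||` and the tests use `mu2 = mu4 = 50`.

Hyperparameters are cohort-dependent. `random_search()` implements the
search protocol published with the method (uniform draws from per-parameter
grids; after the first step each parameter keeps the incumbent best value
with probability 1/2), and the synthetic-cohort experiments in the test
suite use `gamma1` and `r1` selected by exactly that search (5-fold CV on
training participants of tuning cohorts, seed 999) rather than the ADNI
values — on the synthetic world the per-participant PCA pull carries
little information (histories are short, so any basis containing them is
PCA-optimal) and the search correctly shrinks it.

## The synthetic cohort generator

`simulate_cohort()` replaces the access-restricted clinical data. Its
stated world:

* A shared latent representation `G_star` (`r2_true x n`, standard normal)
  drives all three views.
* SNPs: `X_SNP = H0_star G_star + noise`, with `H0_star` nonzero only on
  `active_group_count` of the `K` groups.
* Clinical scores: `Y = t(U_star) G_star + noise` for the labeled subset.
* Imaging: a shared orthonormal basis `Q` (`d x r1_true`) maps latent
  trajectories into feature space. Participant `i` starts at a random
  latent point and drifts linearly toward an endpoint `M G_star[, i]`;
  history visits get latent jitter (`traj_jitter_sd`) so they genuinely
  span the subspace; the last record sits at the trajectory endpoint (plus
  measurement noise) and therefore encodes the participant's shared
  representation.
* Visit counts are drawn from `visit_count_range`; the latest scan is then
  discarded with probability `p_discard_last` (default 0.5, mirroring the
  deliberate 50% discard of the final ADNI timepoint in the method's
  original evaluation). A
  discarded scan truncates the trajectory before its endpoint, so exact
  endpoint encoding holds only for retained scans — that is the point of
  the exercise.
* `inject_outliers()` corrupts whole visit columns with heavy-tailed t(2)
  noise, matching the column-wise robustness the L2,1 terms target.

Defaults (`n = 80`, 2 x 45 imaging features, 40 SNPs in 8 groups, 2
scores, `r1_true = r2_true = 3`, 4 scans per participant,
`noise_sd = 0.5` on unit-scale signal) depict a mid-sized ROI panel:
feature dimension comparable to the number of participants, measurement
noise well below between-subject variance (regional imaging measures are
reliable), few visits. An earlier, lower-dimensional default
(`d = 30, n = 50`) turned out to contradict the premise the generator
exists to emulate: with so few features even the *true-subspace* projection
of the last record predicted no better than ridge on the raw features, so
no enrichment method could show its value there. The world was widened
once, on that analysis, and not revisited.

What a green test does **not** establish: the generator shares one
subspace across participants and has no participant-specific signal
directions, no LD correlation structure within SNP groups, no genotype
discreteness, no realistic score marginals. Conclusions transfer to the
statistical shape of the problem, not to any particular cohort.

## Downstream evaluation

`evaluate_downstream()` predicts each clinical score from a fixed-length
representation with ridge regression (closed form, penalty selected by
k-fold CV over `10^3 .. 10^-3`) or, as the nonlinear comparator, kernel
ridge regression with RBF or sigmoid kernel — a stand-in for support
vector regression, which would require an SVM solver this package does not
depend on; the box-constraint grid maps to the inverse ridge penalty.
Selection never touches test labels (asserted by a shuffling test).

`run_experiment()` reproduces the evaluation protocol: 80/20 split, a
transductive fit (imaging and SNP features of all participants visible,
clinical scores of the training participants only), then test RMSE from
the enriched and from the original last-visit representation. Original
features are z-scored for the regression; enriched coordinates are
centered but not rescaled — they come from orthonormal projections of
standardized data and are already commensurate, and rescaling would
inflate low-variance (noise) projection directions.

## Known limitations

* The asymmetric bilinear form of the split objective is implemented
  exactly as printed; it coincides with the symmetric surrogate only at
  `A = U`, `B = W`, and before the penalties grow the sweep relies on the
  proximal safeguard rather than on convexity.
* Monotone descent of the true objective is empirical, not proven; the
  solver enforces it by early stopping with stiffer retries.
* With `gamma2 = gamma4 = 0`, `G1`'s scale is unidentified (only
  `t(U) G1` matters); the solver keeps `G1` fixed in that degenerate case.
* The inductive setting (enriching participants unseen at fit time) is out
  of scope; the model is transductive by design.
* Group importance reports the mean of member SNP scores (configurable to
  sum); the per-SNP weight is the row-L1 of `H0`, the direct analogue of
  the imaging definition — no published formula exists for the SNP side.
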