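# longenrich

Semi-supervised **longitudinal enrichment** of imaging-genetic data: learn a
participant-specific projection that compresses a variable-length history of
multi-modal neuroimaging visits into one fixed-length biomarker vector,
jointly with a group-sparse factorization of static SNP genotypes and
partially observed clinical scores.

## Who this is for

Analysts of longitudinal cohort studies (e.g. dementia cohorts with repeated
MRI, SNP genotypes and cognitive test scores) who need fixed-length,
predictive participant representations but whose participants have
*different numbers of visits* — the usual obstacle that forces record
deletion or imputation.

## The model

Participant `i` contributes a history `X_i` (d features × n_i visits,
n_i varies), a last record `x_i`, a static SNP profile, and — for the
training subset only — clinical scores. The method learns projections
`W_i` (d × r1, orthonormal columns) and factor matrices by minimizing

```
||F − UᵀG1||₂,₁  + γ₁ Σᵢ ||Xᵢ − WᵢWᵢᵀXᵢ||₂,₁ + γ₂ ||Z − H1G1||₂,₁
                 + γ₃ ||X_SNP − H0G0||₂,₁    + γ₄ ||G1 − G0||₂,₁
                 + γ₅ Σₖ ||H0ᵏ||_F           + γ₆ (||W₍₁₎||★ + ||W₍₂₎||★)
                 + γ₇ ||U||₁
s.t.  F_l = Y_l,   WᵢᵀWᵢ = I,
```

where `Z = [W₁ᵀx₁, …, Wₙᵀxₙ]` is the enriched matrix, `||·||₂,₁` sums row
Euclidean norms (robustness to outlying rows), `||·||★` is the trace norm
coupling all projections, and `H0ᵏ` are SNP-group row blocks (group
sparsity). The non-smooth objective is solved by iterative reweighting with
an inner ADMM (copies `A = U`, `Bᵢ = Wᵢ`; closed-form / linear-system /
Sylvester block updates). `vignettes/longenrich-methods.Rmd` documents the
model, the solver safeguards and every design decision.

The enriched vectors `zᵢ = Wᵢᵀxᵢ` feed conventional regressors
(`evaluate_downstream()`: ridge, or kernel ridge standing in for SVR), and
the fitted weights rank biomarkers: imaging feature `q` scores
`Σᵢ ||e_qᵀWᵢ||₁`, SNPs score by the row-L1 of `H0`, aggregated per group.

## Worked example

Simulate a cohort with the statistical structure the model assumes (shared
low-dimensional participant representation driving imaging, SNP and score
views; 4 scans per participant with the latest discarded with probability
0.5; group-sparse SNP loadings), then run the full evaluation protocol —
transductive fit, 80/20 split, cross-validated ridge on both the enriched
and the original last-visit representation:

```r
library(longenrich)

sim <- simulate_cohort(sim_config(l = 80, seed = 205))  # n = 80, fully labeled
hp  <- hyperparams(r1 = 8, gamma1 = 1e-2, max_outer = 3, max_inner = 40)
rep <- run_experiment(sim$cohort, hp, seed = 5)
print(rep)
#> Enrichment prediction experiment
#>   train/test     : 64 / 16 participants
#>   score1   RMSE original 0.9779 | enriched 0.8016 (-18.0%)
#>   score2   RMSE original 1.0005 | enriched 0.9338 (-6.7%)

imp <- snp_importance(rep$fit$state$H0, sim$cohort$snp_groups)
head(imp$group, 3)
#>   group size    score       sd rank
#> 5     5    5 7.18e-05 2.99e-05    1
#> 2     2    5 4.82e-05 1.83e-05    2
#> 4     4    5 1.18e-05 4.80e-06    3
sim$truth$active_groups
#> [1] 2 5
```

The enriched representation predicts both held-out scores with lower RMSE
than the raw last visit (−18.0% and −6.7% here), and the two SNP groups
carrying true signal (2 and 5) rank first and second. `gamma1` and `r1`
above were selected by the package's own cross-validated random search
(`random_search()`, incumbent-retaining randomized grid search) on tuning
cohorts;
the remaining hyperparameters are the published defaults.

## Command line

`inst/cli/longenrich.R` exposes `simulate`, `fit`, `importance`,
`evaluate` / `experiment` subcommands over the on-disk cohort format
(JSON manifest + CSV/TSV tables, see `?write_cohort`):

```sh
Rscript inst/cli/longenrich.R simulate --out cohort/ --seed 3 --n 40
Rscript inst/cli/longenrich.R experiment --cohort cohort/cohort.json \
    --out report.json --seed 3 --allow-nonconverged
```

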