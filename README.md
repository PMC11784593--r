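# mscolor

Sparse multi-stage multi-task mixed-effects **co**llaborative
**lo**ngitudinal **r**egression for imaging genetics: joint modeling of
staged disease-progression trajectories from longitudinal neuroimaging
quantitative traits (QTs) and sparse identification of the genetic
variants underpinning them, with power borrowed from external GWAS
summary statistics.

## Who this is for

Statistical geneticists and imaging-genetics researchers with a
longitudinal cohort (repeated imaging QTs, e.g. regional cortical
thickness, plus genotypes) who want to (i) model a disease trajectory
whose rate of change differs between progression stages, and (ii) rank
candidate variants per stage, while leveraging published per-SNP effect
sizes from a much larger single-visit GWAS through a reference LD panel
— no individual-level GWAS data needed.

## The model

Per stage `s` and within-stage visit time `t_ks` (months), the QT matrix
`Z_ks` (subjects × QTs) is modeled as

```
Z_ks ≈ γ (X_s W_s + X_s V_s t_ks) + (1 − γ)(A_s + B_s t_ks)
```

with standardized genotypes `X_s` (subjects × SNPs), per-stage genetic
intercept/slope effect matrices `W_s`, `V_s` (SNPs × QTs), and
subject-level aging intercepts/slopes `A`, `B` shared across stages
through the subject registry. A per-stage joint SNP effect vector `u_s`
is tied to the external marginal effects `β` through the reference-panel
LD matrix `Σ̂` by the term `τ (n_ref − 1)(u_sᵀ Σ̂ u_s − 2 u_sᵀ β)`. Rows
of the stacked blocks `P_s = [u_s W_s]` and `Q_s = [u_s V_s]` are
selected jointly by an `ℓ∞,1` penalty (sum of row maxima), solved by
alternating closed-form updates with iterative diagonal reweighting — so
a variant with strong GWAS support keeps its imaging effects alive, and
vice versa.

Three comparison methods share the data model and evaluation harness:
per-timepoint sparse multi-task regression (`fitSMTR`), the one-stage
mixed-effects longitudinal model (`fitSMML`), and the multi-stage model
without the GWAS term (`fitMSMML`).

## Worked example

Simulate the package's reference study — a three-stage cohort (200
subjects per stage, 80% carry-over) with 100 SNPs of which 10 are
causal, plus a paired 20 000-subject GWAS and a 500-subject reference
panel — then fit the collaborative model and score variant selection
against the simulated truth:

```r
library(mscolor)

study <- simulateStudy(simConfig(seed = 1))
study$data
#> LongitudinalDataset: 3 stages, 280 registry subjects, 100 SNPs, 4 QTs
#>   per-stage n: 200, 200, 200
#>   covariates: age, gender, education, handedness, diagnosis, mmse, adas, ravlt_tot, ravlt_30, ravlt_rec

fit <- fitMSColoR(study$data, study$harmonized, lambdaP = 10, lambdaQ = 10)
fit
#> MscolorFit: 3 stages, 100 SNPs, 4 QTs, 280 registry subjects
#>   gamma = 0.5, lambdaP = 10, lambdaQ = 10, tau = 1
#>   200 iterations, converged: FALSE, final objective 1375.1

sel <- selectionMetrics(fit, study$truth)
sel
#> SelectionReport: 100 SNPs, top 10
#>   support-recovery AUC 0.984, precision@10 0.800
```

The fitted per-subject slopes separate the stages and correlate with the
synthetic cognitive scores, mirroring the downstream analyses such a
model supports:

```r
head(trajectoryCorrelations(fit, covariates(study$data),
                            c("mmse", "diagnosis")), 4)
#>   stage   measure     score   n          r            p band
#> 1     1     slope      mmse 200 0.26652882 1.362382e-04  ***
#> 2     1     slope diagnosis 200 0.36784609 8.387224e-08 ****
#> 3     1 intercept      mmse 200 0.20741879 3.207936e-03   **
#> 4     1 intercept diagnosis 200 0.05720569 4.210512e-01   ns
```

The full harness — nested 5×5-fold cross-validation with the `10^(-3..3)`
sparsity grid, per-fold selection scoring, stage-contrast t tests —
is one call per method:

```r
cv <- nestedCV(study$data, study$harmonized, method = "mscolor",
               maxIter = 60, seed = 1)
cv
#> CvReport ('mscolor'): 5 outer folds, grid of 7 values
#>     metric      mean          sd
#>  trainRmse 0.5527467 0.004446185
#>   testRmse 0.9014084 0.021192474
```

Interpretation: test RMSE is on the standardized QT scale, so 0.90 means
the model predicts held-out subjects' trajectories from genotype plus
the population aging curve to within 0.90 within-cohort standard
deviations — against ≈ 1.0 for the baselines without the GWAS term. A
support-recovery AUC near 1 means the causal SNPs outrank essentially
every null SNP (cross-validated fold scores, as reported by
`selectionMetrics(cv, study$truth)`, reach AUC 1.0 on this study).
Diagnosis in the correlation table is numeric-coded by sorted level
names; use an ordinal recoding for directional interpretation.

A thin command-line wrapper (`inst/scripts/mscolor`) exposes
`simulate`, `fit` and `evaluate` subcommands over YAML run configs; see
`?runSimulate`, `?runFit`, `?runEvaluate`.

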