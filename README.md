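# irsabp

Metaheuristic-seeded neural-network training for binary clinical
classification in R.

Small backpropagation ("BP") networks on tabular clinical data — the
canonical example being Pima-style diabetes screening with eight numeric
predictors (Pregnancies, Glucose, Blood Pressure, Skin Thickness, Insulin,
BMI, Diabetes Pedigree Function, Age) and a 0/1 outcome — are notoriously
sensitive to weight initialization. `irsabp` implements a hybrid trainer
for this setting, aimed at biostatisticians and ML practitioners who want
a reproducible, dependency-light reference implementation:

1. an **improved Reptile Search Algorithm (IRSA)** searches the network's
   flat weight/bias vector over the box `[-3, 3]^d`, minimizing the raw
   training misclassification rate
   `f = 1 - (1/n) Σ I(ŷᵢ = yᵢ)`;
2. the best candidate found seeds ordinary **backpropagation** (full-batch
   accumulation of the per-pattern rule `w ← w − η·δ·h` on squared error).

IRSA augments the baseline RSA (also included, as the comparison variant)
with four devices: cubic chaotic-map initialization `C_{k+1} = μC_k(1−C_k²)`
refined by elite opposition-based learning; golden-ratio blending
`a·Best_j − (1−a)·η_{ij}·β − R_{ij}·r` with `a = (√5−1)/2` in the
encirclement phase; a nonlinear hunting factor `A(t) = arctan(e^{−(t/T)³})`
damping the coordination phase; and a sigmoid-stabilized reduction function
`R_{ij} = (Best_j − x_{r₂,j}) / (Best_j + ξ·σ(t/T))`.

Around that core the package ships the full experimental pipeline: a
Pima-style synthetic table generator with tunable class-separation
(`effect_size`), zero-as-missing mean imputation, stratified 80/20
splitting with largest-remainder rounding, SMOTE oversampling to exact
class balance, min–max normalization, and confusion-matrix / ROC / AUC
evaluation with a Mann–Whitney-exact trapezoidal AUC.

## Worked example

Train IRSA-BP on a synthetic 500-row cohort with a 3-SD class shift on
Glucose and BMI (a regime where the Bayes rule on Glucose alone is ≈ 0.94
accurate), using the reference configuration — population 10, 8 optimizer
iterations, learning rate 0.01, 10000 epochs:

```r
library(irsabp)

tab <- generate_table(synthetic_spec(n_rows = 500, prevalence = 0.35,
                                     effect_size = 3, seed = 1))
tab   <- impute_zero_as_missing_mean(tab)
sp    <- stratified_split(tab, 0.8, seed = 1)
train <- smote_oversample(sp$train, k_neighbors = 5, seed = 1)
norm  <- fit_minmax(train)

model <- train_irsa_bp(apply_minmax(train, norm), network_spec(),
                       irsa_config(seed = 1), train_config())
round(model$search_history, 4)
#> [1] 0.1788 0.1788 0.1788 0.1788 0.1788 0.1788 0.1615 0.1615

evaluate_model(model, apply_minmax(sp$test, norm))
#> <metrics_report> accuracy=0.970 precision=0.921 recall=1.000 f1=0.959 fpr=0.046 auc=0.998
```

`search_history` is the optimizer's best training-error per iteration
(non-increasing by construction): the metaheuristic stage found a starting
point with 16.15% training error, and gradient refinement brought the
*test* accuracy to 0.97 with AUC 0.998. `recall = 1.000` means every
positive test case was detected; `fpr = 0.046` is the false-alarm rate
among negatives.

Head-to-head comparison of the improved and baseline optimizers over
seeded repetitions:

```r
cmp <- compare_optimizers(apply_minmax(train, norm),
                          apply_minmax(sp$test, norm),
                          variants = c("irsa", "rsa"), n_seeds = 10)
cmp[, c("variant", "accuracy_mean", "accuracy_sd", "auc_mean")]
```

A thin command-line wrapper (`exec/irsabp`) exposes the same pipeline as
subcommands (`simulate`, `preprocess`, `train`, `evaluate`, `compare`,
`validate`) driven by a YAML config; `run_pipeline()` is the underlying
function and writes five artifacts (train/test CSVs, model, metrics JSON,
log) that are byte-reproducible under fixed seeds.

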