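---
title: "Methods: chaos-enhanced reptile search optimization of BP networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chaos-enhanced reptile search optimization of BP networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irsabp)
```

## The problem

Small feed-forward ("BP") networks trained by gradient descent are sensitive
to their weight initialization: on low-dimensional clinical tabular data a
bad starting point can leave the network in a poor basin for its entire
training budget. `irsabp` treats initialization as a global optimization
problem: a population-based metaheuristic, the Reptile Search Algorithm
(RSA) and an improved variant (IRSA), searches the flat weight/bias vector
of the network for a low-training-error starting point, and ordinary
backpropagation then refines that candidate. The intended use case is
binary clinical classification on Pima-style tables: eight positive-valued
features (Pregnancies, Glucose, Blood Pressure, Skin Thickness, Insulin,
BMI, Diabetes Pedigree Function, Age) and a 0/1 outcome, with label 1 the
positive (disease-present) class.

## The optimizer

RSA is a crocodile-hunting metaphor over a box-bounded search space. With
population size $N$, iteration budget $T$ and current best solution
$\mathit{Best}$, each coordinate $(i, j)$ is updated once per iteration by
one of four rules, selected by where the iteration $t$ falls in the budget:

* **High walking** ($t \le T/4$):
  $x_{i,j} \leftarrow \mathit{Best}_j - \eta_{i,j}\,\beta - R_{i,j}\,r$,
* **Belly walking** ($T/4 < t \le T/2$):
  $x_{i,j} \leftarrow \mathit{Best}_j \, x_{r_1,j}\, \mathit{ES}(t)\, r$,
* **Hunting coordination** ($T/2 < t \le 3T/4$):
  $x_{i,j} \leftarrow \mathit{Best}_j \, P_{i,j}\, r$,
* **Hunting cooperation** ($3T/4 < t \le T$):
  $x_{i,j} \leftarrow \mathit{Best}_j - \eta_{i,j}\,\epsilon - R_{i,j}\, r$,

where $r \sim U(0,1)$, $\eta_{i,j} = \mathit{Best}_j P_{i,j}$ is the
hunting operator, $P_{i,j} = \alpha + (x_{i,j} - \bar{x}_i) /
(\mathit{Best}_j(\mathit{UB}_j - \mathit{LB}_j) + \epsilon)$ the percent
difference from the best, $R_{i,j} = (\mathit{Best}_j - x_{r_2,j}) /
(\mathit{Best}_j + \epsilon)$ the reduction function, and $\mathit{ES}(t) =
2 r_3 (1 - t/T)$ with $r_3 \in \{-1, 0, 1\}$ the evolution factor.

IRSA modifies four ingredients:

1. **Initialization.** Instead of a uniform draw, candidates are placed by
   a cubic chaotic map $C_{k+1} = \mu C_k (1 - C_k^2)$ (defaults $C_0 =
   0.3$, $\mu = 2.595$, ergodic on $(0,1)$), consumed row-major across the
   population. An *opposite* population $x' = C(\mathit{LB} + \mathit{UB})
   - x$ is then formed and each candidate is replaced by its opposite when
   the opposite evaluates better (elite opposition-based learning).
2. **Golden-ratio encirclement.** Both exploration rules blend the best
   solution by the golden-section constant $a = (\sqrt 5 - 1)/2 \approx
   0.618$: high walking becomes $a\,\mathit{Best}_j - (1-a)\eta_{i,j}\beta -
   R_{i,j} r$ and belly walking is scaled by $a$.
3. **Nonlinear hunting factor.** Coordination steps are damped by
   $A(t) = \arctan\!\bigl(e^{-(t/T)^3}\bigr)$, which decreases from $\pi/4$
   to $\arctan(e^{-1})$, weaning the search off the incumbent best late in
   the run.
4. **Sigmoid-stabilized reduction.** The reduction denominator becomes
   $\mathit{Best}_j + \xi\,\sigma(t/T)$ with $\sigma$ the logistic
   function, so the stabilizer grows smoothly over the run instead of
   staying at a fixed tiny constant.

### Loop semantics and reproducibility

Iteration 1 is the initial evaluation; update sweeps run from $t = 2$ to
$T$. The best-so-far solution is elitist (never worsens), which makes the
recorded history non-increasing by construction. Within an iteration all
neighbor lookups ($x_{r_1}$, $x_{r_2}$) and the per-candidate mean
$\bar{x}_i$ use a snapshot of the population taken at the iteration start,
and random draws are consumed in a fixed iteration-major,
individual-major, coordinate-minor order, so a run is bit-reproducible
from its seed. $\mathit{ES}(t)$ is drawn once per iteration (it is a
per-iteration stochastic ratio); `rand`, $r_1$ and $r_2$ are redrawn per
coordinate. Every updated coordinate is clipped into
$[\mathit{LB}, \mathit{UB}]$ — the multiplicative updates can otherwise
escape the box.

Two printed ambiguities in the source material were resolved as follows.
The exploration and exploitation windows overlap as printed; the classic
four-quarter partition above is used. The golden ratio is printed as
"(5-1)/2"; it is read as the golden-section constant $(\sqrt 5 - 1)/2$,
since a blending ratio must lie in $(0,1)$. The nonlinear factor's
exponent is read as $e^{-(t/T)^3}$ (the cube applies to the ratio), and
the sigmoid stabilizer's argument is the iteration ratio $t/T$.

## The network and the hybrid trainer

The default architecture is 8–8–2: one input per clinical feature, eight
hidden sigmoid units, and one sigmoid output node per class (one-hot
targets; label 1 maps to $(0,1)$). The flat encoding walks consecutive
layer pairs in order, weights row-major by source node, then biases —
$8 \times 8 + 8 + 8 \times 2 + 2 = 90$ parameters for the default network,
which is also the dimension of the optimizer's search box $[-3, 3]^{90}$.

The fitness minimized by the search is the raw training misclassification
rate $f = 1 - \frac{1}{n}\sum_i I(\hat y_i = y_i)$. Candidates are *not*
gradient-trained inside the fitness evaluation: with the reference budget
($N = 10$, $T = 8$) that would conflate the two stages and make the small
evaluation budget meaningless. The best vector found seeds a single
backpropagation run.

Backpropagation minimizes the squared-error loss with the classic
per-pattern rule $w \leftarrow w - \eta\,\delta\,h$. One epoch applies the
accumulated per-pattern updates in a single batch step — equivalently, the
step is $\eta$ times the gradient of the *summed* squared error
$\tfrac12\sum_i \lVert \hat y_i - y_i\rVert^2$. The scaling convention
matters: at the reference learning rate $\eta = 0.01$ a step on the
*mean*-scaled loss is $n$ times smaller and visibly undertrains within the
10000-epoch budget (training accuracy plateaus around 0.91 on the easy
synthetic task, versus 0.97+ for the summed convention and for a logistic
baseline). The recorded loss history is reported on the mean scale
$\frac{1}{2n}\sum_i \lVert \hat y_i - y_i \rVert^2$, which differs only by
the constant factor $n$; it is observed to be monotonically non-increasing
at $\eta = 0.01$ on both 32-row and ~500-row batches. Training stops at
the epoch budget or when the loss improves by less than $10^{-12}$ over
100 epochs. Predicted labels take the larger output node, with exact ties
resolved to class 0; the ROC score is the class-1 node's activation.

## Reference parameters

| Parameter | Default | Meaning |
|---|---|---|
| $N$ | 10 | population size |
| $T$ | 8 | optimizer iterations |
| $\mathit{LB}, \mathit{UB}$ | $-3, 3$ | search box per weight |
| $\alpha$, $\beta$ | 0.1, 0.1 | hunting / exploration precision constants |
| $\epsilon$ | $10^{-10}$ | reduction-denominator guard (baseline) |
| $\xi$ | $10^{-6}$ | sigmoid-stabilizer scale (improved) |
| $a$ | $(\sqrt5-1)/2$ | golden-section blending constant |
| $C_0$, $\mu$ | 0.3, 2.595 | cubic chaotic map |
| $\eta$ (learning rate) | 0.01 | backpropagation step size |
| epochs | 10000 | backpropagation budget |
| hidden nodes | 8 | network width |
| $k$ | 5 | SMOTE nearest neighbors |
| train fraction | 0.8 | stratified 80/20 split |

$\epsilon$ and $\xi$ are not stated in the source material; the defaults
are conventional magnitudes and both are configurable.

## Preprocessing

Zeros in Blood Pressure, Skin Thickness and Insulin encode missing
measurements and are replaced by the mean of the *nonzero* entries of
their column — a mean contaminated by the zero placeholders would defeat
the imputation. Min–max normalization rescales each feature by the fitted
extrema; columns constant at fit time map to 0 with a warning. The split
is stratified with largest-remainder rounding (so 769 rows at 80% give
exactly 615/154), and SMOTE appends interpolated minority rows
($s + \lambda(n - s)$, $\lambda \sim U[0,1]$, $n$ one of the $k$ nearest
minority neighbors) until the classes balance exactly.

Two scope choices are deliberately leak-averse defaults with faithful
alternatives: normalization is fitted on the training part only
(`normalize_on = "full"` mimics a single-pass reading), and SMOTE runs on
the training part after the split (`smote_scope = "full"` reproduces the
balance-then-split reading). Neither alternative is asserted to be the
source procedure; both are supported.

## The synthetic generator

Real Pima-style data cannot ship with the package, so every stage is
exercised on synthetic tables whose shape mimics the published summary
statistics: Poisson pregnancies (mean 3, capped at 15), clipped Gaussian
glucose (110, 30), blood pressure (70, 12), skin thickness (29, 10) and
BMI (32, 7), log-normal insulin, gamma pedigree, shifted-exponential age
with a hard floor at 21, zero-inflation of the three missingness-prone
columns at realistic rates (5% / 30% / 49%), and ~35% positive labels.

Labels threshold a pure-noise latent at the $(1 - p)$ quantile, so class
counts hit the target prevalence up to rounding, and the positive class's
Glucose and BMI are then shifted upward by `effect_size` within-class
standard deviations. This makes `effect_size` the *only* carrier of label
signal: at 0 the features are provably uninformative (any classifier's
expected accuracy is the majority rate), and the Bayes rule is an
analytic two-Gaussian threshold on the shifted columns. An earlier design
in which the latent score itself mixed standardized Glucose/BMI/Age was
rejected because residual feature–label correlation at zero effect size
breaks that calibration property. Shifted values are intentionally not
re-clipped: re-clipping would silently compress the configured
separation. The generator does **not** model real inter-feature
correlation structure, longitudinal records, or measurement error, so
passing tests demonstrate the mechanics of the pipeline and optimizer —
not clinical performance on real cohorts.

## Problem sizes used in the tests

The shipped tests and the results script run at desk scale, chosen so the
whole suite completes in a few minutes while keeping every check
statistically meaningful: sphere benchmarks at $n \in \{2, 5\}$ with 10–20
seeds; gradient checks on 4–3–2 networks over 20 seeds; end-to-end
classification on 500-row tables at `effect_size = 3` (a regime where the
Bayes accuracy on Glucose alone is ≈ 0.94) over 10 seeds; generator
marginal checks on $10^4$-row draws. The end-to-end runs use the full
reference configuration of the table above, including the 10000-epoch
refinement budget.

## Known limitations

* The reference iteration budget ($T = 8$) makes the metaheuristic stage a
  coarse initializer, not a complete trainer; most of the final accuracy
  is delivered by the gradient phase. This mirrors the intended role
  split.
* The belly-walking rule is purely multiplicative, so whenever the
  evolution factor draws $r_3 = 0$ an entire sweep collapses candidates to
  the origin. On objectives whose optimum is at the origin (the sphere
  benchmark) this shortcut reaches the exact optimum; on real weight
  spaces it simply acts as an occasional restart near zero.
* Precision/recall/F1/FPR fall back to 0 with a warning when their
  denominator is empty; reports on degenerate folds are deterministic
  rather than undefined.
* The comparison harness reports means and standard deviations over seeds;
  with 10 seeds the IRSA-vs-RSA accuracy gap on easy synthetic tasks is
  small and can fall within noise. The directional claim is therefore
  tested with a 0.02 margin.
* AO (Aquila/Skyhawk) and MPA comparator optimizers are not implemented;
  `rsa_optimize()`'s signature (objective, space, config, variant) is the
  plugin surface a third-party optimizer would mimic.
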