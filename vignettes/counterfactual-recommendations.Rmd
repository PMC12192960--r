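---
title: "Multi-objective counterfactual recommendations: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-objective counterfactual recommendations: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multicf)
```

## The model

`multicf` generates feature-value recommendations that reduce the predicted
probabilities of several diseases *at once*. Each disease *i* contributes a
black-box probability model $M_i(X_i)$ trained on its own feature set
$X_i$; the sets overlap (in the two-disease setting the package defaults to,
age, average glucose level and BMI are shared), so recommendations that help
one disease can hurt another. The search runs over the union
$X_\Delta = \bigcup_i X_i$, and a solution is a full assignment over
$X_\Delta$; each model sees only the projection onto its own columns.

Three layers of constraints shape the box each gene may move in:

1. **Default bounds** $[LB_\delta, UB_\delta]$ per continuous feature,
   declared in the feature registry (clinically plausible ranges).
2. **Immutability**: features the user cannot change are pinned,
   $LB_\delta = UB_\delta = C_\delta$. They are excluded from variation
   entirely — crossover and mutation never touch them — rather than being
   re-clipped after the fact, so the guarantee is exact by construction.
3. **Value windows**: an explicit $[LB'_\delta, UB'_\delta]$, or an anchor
   value $v$ from which the default ±10 % window
   $[0.9v,\ 1.1v]$ is derived (`window_fraction = 0.10`). Windows are
   clipped to the default bounds; the window applies multiplicatively, so a
   negative anchor flips the endpoint order before clipping.

The optimiser is an elitist non-dominated-sorting genetic algorithm
(NSGA-II) minimising the objective vector
$(M_1(x), \dots, M_n(x))$, implemented from scratch in this package:
pairwise Pareto dominance, fast non-dominated sorting, crowding distance,
binary tournament under the crowded-comparison order, simulated binary
crossover (SBX) and polynomial mutation for continuous genes, and elitist
environmental selection of the top $N$ from parents ∪ offspring.

The final front is ranked by the penalty
$$\mathcal{L}(x) = w_1 P_1(x) + w_2 P_2(x) +
  \lambda \max(0, P_1(x) - P_2(x)),$$
with $w_1 = w_2 = \lambda = 1$ by default. The gap term is deliberately
asymmetric — it penalises leaving the *first-listed* disease riskier — which
is why `penalty_config()` requires an explicit `disease_order` rather than
inferring one. Whether a symmetric gap $|P_1 - P_2|$ was ever intended is
unknowable from the published arithmetic, which the asymmetric form
reproduces exactly; the literal form is implemented. For $n > 2$ the gap
generalises to $\sum_{i<j} \max(0, P_i - P_j)$, which reduces to the
two-disease form at $n = 2$; this generalisation is this package's own,
documented extension. The penalty ranks the front *post hoc*; it is not part
of the GA fitness, whose objectives stay the raw probability vector.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `population_size` | 100 | individuals per generation (N); even, ≥ 4 |
| `max_generations` | 40 | fixed-length termination |
| `crossover_probability` | 0.9 | per parent pair |
| `sbx_eta` | 15 | SBX distribution index; larger keeps offspring near parents |
| `mutation_probability` | 1/k | per gene, k = number of free genes |
| `mutation_eta` | 20 | polynomial-mutation index |
| `tournament_size` | 2 | binary tournament |
| `window_fraction` | 0.10 | anchor-derived window half-width (±10 %) |
| `weights`, `lambda` | 1, 1 | penalty coefficients |

The operator suite and its indices are the canonical NSGA-II choices; the
underlying algorithm statement specifies only "crossover and mutation", so
these are declared defaults, all configurable, not inferred intent. The same
applies to initialisation (uniform within bounds) and tie-breaking.

## Numerical and design choices

- **Mixed genome encoding.** Continuous genes are reals; binary genes
  integers in {0, 1}; categorical genes integer category indices. SBX is
  undefined off the real line, so binary/categorical genes use uniform
  exchange crossover and uniform re-draw mutation. Models that need one-hot
  inputs get them from their own fitted preprocessing inside the adapter, so
  the genome stays label-encoded.
- **Out-of-bounds offspring are clipped** to the boundary, not resampled:
  deterministic and bound-preserving.
- **Termination** is `max_generations` only; an optional no-improvement
  early stop (`early_stop_generations`) exists but is off by default, so a
  run's length is predictable and reproducible.
- **Duplicates are permitted** in the population and on the front — distinct
  recommendations with identical probabilities are meaningful output.
- **Crowding-distance ties at truncation.** Boundary members of a front get
  infinite crowding; when the straddling front must be cut inside a group of
  equal crowding values, members holding a front-wise objective minimum are
  kept first (then stable index order). This makes the per-generation
  minimum of each objective non-increasing under deterministic models — the
  elitism property the tests assert — even in the rare tie configurations
  where textbook truncation could drop an extreme.
- **Degenerate inputs.** A window collapsing to a point behaves like a fixed
  feature for the operators; a window entirely outside the default bounds is
  a configuration error; an anchor outside the defaults collapses its window
  onto the nearest bound. Zero-range objectives contribute nothing to
  crowding. Fronts of ≤ 2 members are all-infinite.
- **Metric conventions.** Error metrics (MAE/MSE/RMSE/R²) and accuracy are
  computed on hard 0/1 predictions (threshold 0.5), which forces the
  identities MAE = MSE = 1 − accuracy and RMSE = √MSE; ROC AUC uses the
  continuous scores under its standard definition. Model selection takes the
  highest ROC AUC, ties broken by accuracy then candidate order. No
  class-imbalance resampling is applied by default.
- **±10 % window rule.** The literal multiplicative rule is implemented
  (anchor 20.10 → [18.09, 22.11]); it is applied consistently even where
  informal descriptions of such windows are arithmetically looser.

## What the synthetic generator emulates — and what it does not

`generate_problem()` mirrors the structure of the public stroke/diabetes
case: a 15-feature union (10 stroke features, 8 diabetes features, exactly
three shared continuous features), mixed continuous/binary/categorical
columns, and binary outcomes. One master subject table is drawn and
projected per disease, so shared features agree subject-by-subject. Outcomes
are Bernoulli under a *logistic* ground truth whose coefficients act on
bound-normalised features, with magnitudes in [−2, 2] by default so
probabilities span (0, 1) non-degenerately and the intercept centred for
prevalence ≈ ½.

The logistic truth is chosen because its box-constrained minima are analytic
(each free monotone coordinate sits at the bound opposite its coefficient
sign; `analytic_optimum()`) and its two-disease Pareto front is computable
exactly: features exclusive to one disease cannot trade off against the
other, so they are pinned at their own optimum and the front is traced by
grid-enumerating only the shared free features (`analytic_pareto()`, with a
10⁶-point guard on the grid). That turns convergence and recovery claims
into checkable assertions.

What the generator does *not* emulate: the real datasets' marginal
distributions, feature correlations, class imbalance (real stroke prevalence
is a few percent, not one half), or missingness patterns beyond an optional
uniform null-injection switch. Passing the recovery tests therefore shows
the optimiser finds the optima of smooth, monotone risk surfaces under box
constraints — it does not certify behaviour on the idiosyncrasies of any
real clinical table, and tree-ensemble models fitted to such tables can
present far less smooth objective landscapes.

## Problem sizes used by the shipped checks

The test suite exercises oracle equivalence on random populations of up to
200 members (2–3 objectives, brute-force O(n²) oracles re-implemented
independently in the test helpers), convergence on the default synthetic
problem at population 500 for 40 generations, and full-pipeline parameter
recovery at 5 000 training rows with population 200 for 40 generations —
sizes at which the analytic oracles are exact and the whole suite runs in
about a minute on one core. Recovery asserts achieved true risks within 0.05
absolute of the analytic minima and a directed nearest-neighbour distance of
at most 0.05 from the found front to the analytic front in objective space.

## Known limitations

- Recommendations respect only box bounds and fixedness. There are no
  plausibility or causal constraints: if the models reward an extreme but
  in-bounds insulin value, the method reports it literally. Downstream
  clinical filtering is out of scope.
- The penalty ranks but does not steer the search; with many objectives the
  front grows and `n_cf` selection becomes the user's main lever.
- Categorical genes re-draw uniformly under mutation, which ignores any
  ordinal structure a category set might have.
- ROC-AUC model selection on a held-out split is as good as the split;
  no cross-validation is built in.
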