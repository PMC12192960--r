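# multicf

Multi-objective counterfactual recommendations for disease risk models.

## The problem

A counterfactual explanation answers the question a patient actually asks of
a risk model: *what should I change so the model stops predicting I am at
risk?* Classical counterfactual methods work one model at a time, which
breaks down for comorbid conditions — lowering the glucose or BMI a diabetes
model wants may raise the risk a stroke model sees, because the models share
features. `multicf` treats the problem as what it is: a constrained
multi-objective optimisation over the **union** of the per-disease feature
sets.

Given diseases *i = 1, …, n* with trained probability models
*M_i(X_i)* over (overlapping) feature sets *X_i*, the search space is
*X_Δ = X_1 ∪ … ∪ X_n* with per-feature box bounds
*LB_δ ≤ x_δ ≤ UB_δ*. Users declare **infeasible** features they cannot
change (age, gender, …), which are pinned to constants
*LB_δ = UB_δ = C_δ*, and may restrict feasible continuous features either
with explicit windows *[LB′_δ, UB′_δ]* or by anchoring a current value *v*,
which gives the default window *[0.9·v, 1.1·v]* (±10 %).

An elitist non-dominated-sorting genetic algorithm (NSGA-II: fast
non-dominated sorting, crowding distance, binary tournament, simulated
binary crossover, polynomial mutation, elitist (rank, crowding) selection —
all implemented here, with uniform-exchange/re-draw operators for binary and
categorical genes) minimises the objective vector
*(M_1(x), …, M_n(x))* of predicted disease probabilities simultaneously.
The final Pareto front is ranked by the penalty

```
L(x) = w1·P1(x) + w2·P2(x) + λ·max(0, P1(x) − P2(x))
```

with unit weights and λ = 1 by default; the gap term discourages solutions
that leave the first-listed disease disproportionately risky. For *n* > 2
diseases the gap generalises to the sum of positive ordered pairwise gaps
(a documented extension of the two-disease form).

The package also ships the surrounding pipeline — median imputation, one-hot
encoding, an 80:20 split, a pluggable candidate-model zoo (logistic
regression, XGBoost, random forest) selected by ROC AUC behind a black-box
adapter contract — and a synthetic two-disease generator with logistic
ground truth whose box-constrained optima and Pareto fronts are analytic, so
the whole method is testable end to end without external data.

## Worked example

```r
library(multicf)

problem <- generate_problem(n_subjects = 5000, seed = 42)   # stroke + diabetes
models <- list()
for (d in names(problem$tables)) {
  sp  <- split_train_test(problem$tables[[d]], ratio = 0.8, seed = 42)
  fit <- train_and_select(sp$train, sp$test,
                          list(candidate_logistic(), candidate_xgboost()),
                          d, problem$registry, "outcome")
  models[[d]] <- fit$model
}

constraints <- user_constraints(
  fixed   = list(age = 32, gender = "male"),  # immutable features
  anchors = list(bmi = 25))                   # BMI searched in [22.5, 27.5]

run <- run_nsga2(models, problem$union, constraints,
                 nsga2_config(population_size = 200, max_generations = 40,
                              seed = 42))
glance(run)
#>   population_size generations front_size min_stroke min_diabetes min_penalty
#> 1             200          40        200    0.00369       0.0909       0.101

cfs <- select_counterfactuals(run, n_cf = 2)
cf_report(cfs)
#>    feature                    CF_1         CF_2
#>  1 age                        32           32
#>  2 hypertension               no           no
#>  3 heart_disease              no           no
#>  4 avg_glucose_level          299.848      299.217
#>  5 bmi                        22.532       22.522
#>  ...
```

`glance()` shows the best predicted probability reached for each disease
over the run (here 0.4 % stroke, 9.1 % diabetes) and the smallest penalty on
the front. `cf_report()` is the user-facing recommendation table: one column
per counterfactual, fixed features at their constants (age stays 32),
binary/categorical genes rendered as labels, continuous values to three
decimals — and the anchored BMI stays inside its ±10 % window.
`tidy(run)`, `pareto_export(run)`, `autoplot(run)` and
`plot_convergence(run)` expose the front and the per-generation convergence
trace. A command-line wrapper (`inst/scripts/multicf`) chains the same steps
as `generate-data`, `train` and `recommend` subcommands.

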