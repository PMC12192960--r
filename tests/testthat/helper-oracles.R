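# Independent brute-force oracles and small problem builders shared by the
# suite. These re-derive Pareto machinery from first principles and must stay
# free of the package's sorting/selection code paths.

# Dominance from the definition (minimisation).
oracle_dominates <- function(a, b) all(a <= b) && sum(a < b) > 0

# Non-dominated fronts by repeated scanning: O(n^2) per front.
oracle_fronts <- function(obj) {
  remaining <- seq_len(nrow(obj))
  fronts <- list()
  while (length(remaining) > 0L) {
    nd <- vapply(remaining, function(i) {
      !any(vapply(remaining, function(j) {
        j != i && oracle_dominates(obj[j, ], obj[i, ])
      }, logical(1)))
    }, logical(1))
    fronts[[length(fronts) + 1L]] <- remaining[nd]
    remaining <- remaining[!nd]
  }
  fronts
}

# Crowding distance by the textbook formula, written longhand.
oracle_crowding <- function(obj) {
  n <- nrow(obj)
  if (n <= 2L) return(rep(Inf, n))
  d <- numeric(n)
  for (k in seq_len(ncol(obj))) {
    ord <- order(obj[, k])
    rng <- obj[ord[n], k] - obj[ord[1], k]
    if (rng > 0) {
      d[ord[1]] <- Inf; d[ord[n]] <- Inf
      for (pos in 2:(n - 1)) {
        d[ord[pos]] <- d[ord[pos]] +
          (obj[ord[pos + 1], k] - obj[ord[pos - 1], k]) / rng
      }
    }
  }
  d
}

# A minimal single-disease search space: one continuous gene on [0, 1].
toy_union_1d <- function(name = "g") {
  reg <- feature_registry(feature_spec(name, "continuous", 0, 1))
  union_features(list(disease_features("d1", name)), reg)
}

# Two conflicting logistic objectives sharing the single gene x on [0, 1]:
# d1 risk falls in x, d2 risk rises in x.
toy_conflicting_models <- function(union) {
  list(
    make_risk_model("d1", "g", function(raw) stats::plogis(2 - 4 * raw$g),
                    label = "toy1"),
    make_risk_model("d2", "g", function(raw) stats::plogis(-2 + 4 * raw$g),
                    label = "toy2"))
}

# Small three-feature union used by projection tests.
toy_union_3 <- function() {
  reg <- feature_registry(
    feature_spec("a", "continuous", 0, 1),
    feature_spec("b", "continuous", 0, 1),
    feature_spec("c", "binary"))
  union_features(list(disease_features("d1", c("a", "c")),
                      disease_features("d2", c("b", "c"))), reg)
}

# Run the optimiser loop step by step so tests can inspect every generation.
monitored_run <- function(models, union, constraints, config,
                          window_fraction = 0.10) {
  bounds <- resolve_bounds(union, constraints, window_fraction)
  set.seed(config$seed)
  pop <- initialize_population(bounds, config$population_size)
  obj <- evaluate_population(pop, models, union)
  populations <- list(pop)
  for (gen in seq_len(config$max_generations)) {
    sorted <- fast_non_dominated_sort(obj)
    crowd <- numeric(nrow(pop))
    for (idx in sorted$fronts) {
      crowd[idx] <- crowding_distance(obj[idx, , drop = FALSE])
    }
    off <- make_offspring(pop, obj, sorted$rank, crowd, config, bounds)
    off_obj <- evaluate_population(off, models, union)
    sel <- environmental_select(rbind(pop, off), rbind(obj, off_obj),
                                config$population_size)
    pop <- sel$pop; obj <- sel$obj
    populations[[gen + 1L]] <- pop
  }
  list(populations = populations, bounds = bounds, final_obj = obj)
}
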