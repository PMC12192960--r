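test_that("dominance follows the minimisation definition", {
  expect_true(dominates(c(0.1, 0.2), c(0.2, 0.2)))
  expect_false(dominates(c(0.1, 0.3), c(0.2, 0.2)))  # incomparable
  expect_false(dominates(c(0.2, 0.2), c(0.1, 0.3)))
  expect_false(dominates(c(0.1, 0.2), c(0.1, 0.2)))  # irreflexive
  expect_error(dominates(c(1, 2), c(1, 2, 3)), "length")
})

test_that("non-dominated sorting matches hand-derived fronts", {
  obj <- rbind(c(1, 2), c(2, 1), c(2, 2), c(3, 3))
  s <- fast_non_dominated_sort(obj)
  expect_equal(s$fronts, list(c(1L, 2L), 3L, 4L))
  expect_equal(s$rank, c(1L, 1L, 2L, 3L))

  # identical objectives: one front
  same <- matrix(0.5, nrow = 4, ncol = 2)
  expect_length(fast_non_dominated_sort(same)$fronts, 1L)

  expect_error(fast_non_dominated_sort(rbind(c(1, NA))), "NA")
})

test_that("sorting and selection agree with brute-force oracles on random populations", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(10:120, 1)
    m <- sample(2:3, 1)
    obj <- matrix(stats::runif(n * m), n, m)
    s <- fast_non_dominated_sort(obj)
    expect_equal(purrr::map(s$fronts, sort), purrr::map(oracle_fronts(obj), sort))

    # crowding agrees with the longhand formula on the first front
    f1 <- s$fronts[[1]]
    expect_equal(crowding_distance(obj[f1, , drop = FALSE]),
                 oracle_crowding(obj[f1, , drop = FALSE]))

    # environmental selection: whole fronts in rank order, straddling front
    # truncated by descending crowding
    pop <- matrix(0, n, 1, dimnames = list(NULL, "g"))
    k <- sample(seq(2, n - 1), 1)
    sel <- environmental_select(pop, obj, k)
    ranks <- s$rank
    orc_fronts <- oracle_fronts(obj)
    taken <- integer(0); fr <- 0L
    while (fr < length(orc_fronts) &&
           length(taken) + length(orc_fronts[[fr + 1L]]) <= k) {
      fr <- fr + 1L
      taken <- c(taken, orc_fronts[[fr]])
    }
    sig <- function(m) apply(m, 1, paste, collapse = "|")
    sel_rows <- match(sig(sel$obj), sig(obj))
    expect_true(all(taken %in% sel_rows))
    if (length(taken) < k) {
      strad <- orc_fronts[[fr + 1L]]
      cd <- oracle_crowding(obj[strad, , drop = FALSE])
      chosen <- setdiff(sel_rows, taken)
      rejected <- setdiff(strad, chosen)
      if (length(rejected) > 0 && length(chosen) > 0) {
        expect_gte(min(cd[match(chosen, strad)]), max(cd[match(rejected, strad)]))
      }
    }
  }
  expect_error(environmental_select(matrix(0, 2, 1), matrix(0, 2, 2), 5),
               "more members")
})

test_that("crowding distance: boundaries infinite, interior sums cuboid sides", {
  expect_equal(crowding_distance(rbind(c(0, 1))), Inf)
  expect_equal(crowding_distance(rbind(c(0, 1), c(1, 0))), c(Inf, Inf))
  # three collinear points: middle distance (1-0)/1 + (1-0)/1 = 2
  obj <- rbind(c(0, 1), c(0.5, 0.5), c(1, 0))
  expect_equal(crowding_distance(obj), c(Inf, 2, Inf))
  # order-invariance
  perm <- c(3, 1, 2)
  expect_equal(crowding_distance(obj[perm, ]), c(Inf, 2, Inf)[perm])
  # zero-range objective contributes nothing (no gap, no boundary bonus)
  flat <- rbind(c(0, 5), c(0.5, 5), c(1, 5))
  expect_equal(crowding_distance(flat), c(Inf, 1, Inf))
})

test_that("initialization respects bounds, domains and fixed constants", {
  reg <- feature_registry(
    feature_spec("g", "continuous", 0, 1000),
    feature_spec("cat", "categorical", categories = c("a", "b", "c")),
    feature_spec("flag", "binary"))
  u <- union_features(list(disease_features("d", c("g", "cat", "flag"))), reg)
  b <- resolve_bounds(u, user_constraints(fixed = list(flag = 1),
                                          anchors = list(g = 100)))
  set.seed(1)
  pop <- initialize_population(b, 200)
  expect_true(all(pop[, "g"] >= 90 & pop[, "g"] <= 110))
  expect_true(all(pop[, "cat"] %in% 1:3))
  expect_true(all(pop[, "flag"] == 1))

  # all features fixed -> identical individuals
  b2 <- resolve_bounds(u, user_constraints(fixed = list(g = 5, cat = "b", flag = 0)))
  pop2 <- initialize_population(b2, 10)
  expect_equal(unname(unique(pop2)), matrix(c(5, 2, 0), 1))

  # same seed -> identical population
  set.seed(3); a <- initialize_population(b, 50)
  set.seed(3); expect_identical(initialize_population(b, 50), a)

  b$lower[1] <- 2; b$upper[1] <- 1
  expect_error(initialize_population(b, 5), "degenerate")
})

test_that("evaluation projects genomes per disease and is idempotent", {
  u <- toy_union_3()
  models <- list(
    make_risk_model("d1", c("a", "c"), function(raw) stats::plogis(raw$a),
                    "m1"),
    make_risk_model("d2", c("b", "c"), function(raw) stats::plogis(raw$b - raw$c),
                    "m2"))
  b <- resolve_bounds(u)
  set.seed(2)
  pop <- initialize_population(b, 30)
  obj <- evaluate_population(pop, models, u)
  expect_true(all(obj >= 0 & obj <= 1))
  expect_identical(obj, evaluate_population(pop, models, u))

  # perturbing a feature outside a model's set leaves that objective unchanged
  pop2 <- pop; pop2[, "b"] <- pmin(1, pop2[, "b"] + 0.1)
  obj2 <- evaluate_population(pop2, models, u)
  expect_identical(obj2[, "d1"], obj[, "d1"])
  expect_false(identical(obj2[, "d2"], obj[, "d2"]))

  # constant model -> constant objectives
  const <- list(make_risk_model("d1", "a", function(raw) rep(0.5, nrow(raw)), "c"))
  expect_equal(unname(evaluate_population(pop, const, u)[, 1]), rep(0.5, 30))
})

test_that("SBX offspring are symmetric around the parents and respect degeneracy", {
  set.seed(17)
  n <- 10000
  ch <- multicf:::sbx_gene(rep(0.2, n), rep(0.8, n), 0, 1, eta = 15)
  vals <- c(ch[[1]], ch[[2]])
  expect_lt(abs(mean(vals) - 0.5), 0.01)
  expect_true(all(vals >= 0 & vals <= 1))
  # identical parents: SBX is inert
  same <- multicf:::sbx_gene(rep(0.4, 100), rep(0.4, 100), 0, 1, eta = 15)
  expect_equal(same[[1]], rep(0.4, 100))
  expect_equal(same[[2]], rep(0.4, 100))
})

test_that("offspring stay within bounds and never touch fixed genes", {
  reg <- feature_registry(
    feature_spec("g", "continuous", 0, 1),
    feature_spec("h", "continuous", -3, 5),
    feature_spec("cat", "categorical", categories = c("a", "b", "c")),
    feature_spec("age", "continuous", 18, 100))
  u <- union_features(list(disease_features("d", c("g", "h", "cat", "age"))), reg)
  b <- resolve_bounds(u, user_constraints(fixed = list(age = 32)))
  cfg <- nsga2_config(population_size = 40, max_generations = 1, seed = 5,
                      mutation_probability = 1)
  set.seed(5)
  pop <- initialize_population(b, 40)
  obj <- matrix(stats::runif(80), 40, 2)
  s <- fast_non_dominated_sort(obj)
  crowd <- stats::runif(40)
  for (rep in 1:5) {
    off <- make_offspring(pop, obj, s$rank, crowd, cfg, b)
    expect_equal(dim(off), dim(pop))
    for (j in seq_len(nrow(b))) {
      expect_true(all(off[, b$feature[j]] >= b$lower[j] - 1e-12))
      expect_true(all(off[, b$feature[j]] <= b$upper[j] + 1e-12))
    }
    expect_true(all(off[, "age"] == 32))   # mutation probability 1, still fixed
    expect_true(all(off[, "cat"] %in% 1:3))
  }

  # identical parents + zero mutation -> offspring identical to parents
  clone <- matrix(rep(c(0.5, 1, 2, 32), each = 4), 4,
                  dimnames = list(NULL, c("g", "h", "cat", "age")))
  cfg0 <- nsga2_config(population_size = 4, max_generations = 1, seed = 1,
                       mutation_probability = 0)
  off0 <- make_offspring(clone, matrix(0.5, 4, 2), rep(1L, 4), rep(Inf, 4),
                         cfg0, b)
  expect_equal(unname(unique(off0)), matrix(c(0.5, 1, 2, 32), 1))
})

test_that("the full loop converges on an analytically solvable 1-D problem", {
  u <- toy_union_1d()
  # risk falls monotonically in the gene, so the box optimum is the upper bound
  model <- list(make_risk_model("d1", "g",
                                function(raw) stats::plogis(2 - 4 * raw$g),
                                "mono"))
  run <- run_nsga2(model, u, config = nsga2_config(population_size = 100,
                                                   max_generations = 40,
                                                   seed = 3))
  best <- run$population[which.min(run$objectives[, 1]), "g"]
  expect_lt(abs(best - 1), 1e-2)
  expect_equal(min(run$objectives[, 1]), stats::plogis(-2), tolerance = 1e-3)
})

test_that("two conflicting objectives recover the analytic trade-off curve", {
  u <- toy_union_1d()
  models <- toy_conflicting_models(u)
  run <- run_nsga2(models, u, config = nsga2_config(population_size = 60,
                                                    max_generations = 30,
                                                    seed = 11))
  # grid oracle for the true front: both objectives are monotone in x in
  # opposite directions, so every x is Pareto-optimal and the front is the
  # whole curve
  xs <- seq(0, 1, length.out = 10000)
  curve <- cbind(stats::plogis(2 - 4 * xs), stats::plogis(-2 + 4 * xs))
  front_obj <- run$objectives[run$front, , drop = FALSE]
  d <- apply(front_obj, 1, function(p) {
    min(sqrt((curve[, 1] - p[1])^2 + (curve[, 2] - p[2])^2))
  })
  expect_lt(max(d), 0.01)
  # final front contains no dominated pair
  for (i in seq_len(nrow(front_obj))) {
    for (j in seq_len(nrow(front_obj))) {
      if (i != j) expect_false(oracle_dominates(front_obj[i, ], front_obj[j, ]))
    }
  }
})

test_that("a fixed seed reproduces the run bit-identically and fixed-point problems stay flat", {
  u <- toy_union_1d()
  models <- toy_conflicting_models(u)
  cfg <- nsga2_config(population_size = 20, max_generations = 8, seed = 42)
  r1 <- run_nsga2(models, u, config = cfg)
  r2 <- run_nsga2(models, u, config = cfg)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$population, r2$population)

  # all features fixed: the trace is constant across generations
  rfix <- run_nsga2(models, u, user_constraints(fixed = list(g = 0.3)),
                    nsga2_config(population_size = 10, max_generations = 5,
                                 seed = 1))
  expect_equal(length(unique(rfix$trace$min_d1)), 1L)
  expect_equal(length(unique(rfix$trace$min_d2)), 1L)
})

test_that("per-generation objective minima never increase (elitism)", {
  set.seed(202)
  problem <- generate_problem(400, seed = 77)
  models <- make_truth_models(problem)
  run <- run_nsga2(models, problem$union,
                   config = nsga2_config(population_size = 40,
                                         max_generations = 25, seed = 6))
  for (col in paste0("min_", names(models))) {
    expect_true(all(diff(run$trace[[col]]) <= 1e-12))
  }
})

test_that("optimizer config validates its invariants", {
  expect_error(nsga2_config(population_size = 5), "even")
  expect_error(nsga2_config(population_size = 2), "even")
  expect_error(nsga2_config(max_generations = 0), "max_generations")
  expect_error(nsga2_config(crossover_probability = 1.4), "probabilities")
})
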