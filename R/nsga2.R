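#' Optimiser configuration for the multi-objective search
#'
#' Defaults follow the canonical elitist NSGA-II operator suite: simulated
#' binary crossover (SBX, distribution index 15) with probability 0.9,
#' polynomial mutation (distribution index 20) with per-gene probability 1/k,
#' and binary tournament selection under the crowded-comparison order.
#'
#' @param population_size Even integer >= 4 (N).
#' @param max_generations Number of generations (>= 1).
#' @param crossover_probability Per-pair SBX probability in \[0, 1\].
#' @param mutation_probability Per-gene mutation probability; `NULL` (default)
#'   resolves to 1/k where k is the number of genes.
#' @param sbx_eta SBX distribution index (larger -> offspring closer to parents).
#' @param mutation_eta Polynomial-mutation distribution index.
#' @param tournament_size Tournament size (default 2, binary tournament).
#' @param seed Integer seed; fixes the whole run bit-identically.
#' @param early_stop_generations Optional integer: stop when the minimum
#'   penalty has not improved for this many generations (off by default).
#' @return An `nsga2_config` list.
#' @export
nsga2_config <- function(population_size = 100L, max_generations = 40L,
                         crossover_probability = 0.9,
                         mutation_probability = NULL,
                         sbx_eta = 15, mutation_eta = 20,
                         tournament_size = 2L, seed = 1L,
                         early_stop_generations = NULL) {
  if (population_size < 4L || population_size %% 2L != 0L) {
    stop("population_size must be an even integer >= 4", call. = FALSE)
  }
  if (max_generations < 1L) stop("max_generations must be >= 1", call. = FALSE)
  for (p in c(crossover_probability, mutation_probability)) {
    if (!is.null(p) && (p < 0 || p > 1)) {
      stop("operator probabilities must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(list(population_size = as.integer(population_size),
                 max_generations = as.integer(max_generations),
                 crossover_probability = crossover_probability,
                 mutation_probability = mutation_probability,
                 sbx_eta = sbx_eta, mutation_eta = mutation_eta,
                 tournament_size = as.integer(tournament_size),
                 seed = as.integer(seed),
                 early_stop_generations = early_stop_generations),
            class = "nsga2_config")
}

#' Draw a random initial population inside the resolved bounds
#'
#' Continuous genes are uniform within their box; binary and categorical genes
#' uniform over their (integer-encoded) domain; fixed features sit at their
#' constants in every individual.
#'
#' @param bounds A [resolve_bounds()] tibble.
#' @param n Number of individuals.
#' @return Numeric matrix, one row per individual, columns named by feature.
#' @export
initialize_population <- function(bounds, n) {
  bad <- !bounds$fixed & bounds$lower > bounds$upper
  if (any(bad)) {
    stop("degenerate bounds (lower > upper) for free feature(s): ",
         paste(bounds$feature[bad], collapse = ", "), call. = FALSE)
  }
  k <- nrow(bounds)
  pop <- matrix(0, nrow = n, ncol = k, dimnames = list(NULL, bounds$feature))
  for (j in seq_len(k)) {
    pop[, j] <- if (bounds$fixed[j] || bounds$lower[j] == bounds$upper[j]) {
      rep(bounds$lower[j], n)
    } else if (bounds$kind[j] == "continuous") {
      stats::runif(n, bounds$lower[j], bounds$upper[j])
    } else {
      sample(seq(bounds$lower[j], bounds$upper[j]), n, replace = TRUE)
    }
  }
  pop
}

#' Evaluate every individual under every disease model
#'
#' Each genome is decoded to raw feature values, projected onto each disease's
#' feature subset, and scored by that disease's model; the objective vector is
#' the per-disease predicted probability (minimised).
#'
#' @param pop Population matrix from [initialize_population()].
#' @param models List of `risk_model` objects (one per disease).
#' @param union The [union_features()] search space.
#' @return Numeric matrix, rows = individuals, columns = diseases.
#' @export
evaluate_population <- function(pop, models, union) {
  stopifnot(length(models) >= 1L)
  raw <- decode_population(pop, union)
  obj <- vapply(models, function(m) predict_probability(m, raw),
                numeric(nrow(pop)))
  obj <- matrix(obj, nrow = nrow(pop),
                dimnames = list(NULL, purrr::map_chr(models, "disease")))
  obj
}

#' Pareto dominance (minimisation)
#'
#' `a` dominates `b` when it is no worse in every objective and strictly
#' better in at least one.
#'
#' @param a,b Equal-length numeric objective vectors.
#' @return Logical scalar.
#' @export
#' @examples
#' dominates(c(0.1, 0.2), c(0.2, 0.2))  # TRUE
#' dominates(c(0.1, 0.3), c(0.2, 0.2))  # FALSE (incomparable)
dominates <- function(a, b) {
  if (length(a) != length(b)) {
    stop("objective vectors differ in length", call. = FALSE)
  }
  all(a <= b) && any(a < b)
}

# Pairwise domination matrix: dom[i, j] is TRUE when row i dominates row j.
domination_matrix <- function(obj) {
  n <- nrow(obj); m <- ncol(obj)
  leq <- matrix(0L, n, n); lt <- matrix(0L, n, n)
  for (k in seq_len(m)) {
    v <- obj[, k]
    cmp <- outer(v, v, "<=")
    leq <- leq + cmp
    lt <- lt + (cmp & outer(v, v, "!="))
  }
  (leq == m) & (lt >= 1L)
}

#' Fast non-dominated sorting
#'
#' Partitions a population into successive Pareto fronts: front 1 is the set
#' of members dominated by nobody, front 2 those dominated only by front 1,
#' and so on.
#'
#' @param obj Objective matrix (rows = members, columns = objectives).
#' @return List with `fronts` (list of integer row-index vectors) and `rank`
#'   (integer vector; 1 = non-dominated front).
#' @export
fast_non_dominated_sort <- function(obj) {
  if (anyNA(obj)) stop("unevaluated member: objectives contain NA", call. = FALSE)
  n <- nrow(obj)
  dom <- domination_matrix(obj)
  counts <- colSums(dom)
  rank <- integer(n)
  fronts <- list()
  assigned <- rep(FALSE, n)
  level <- 0L
  while (!all(assigned)) {
    level <- level + 1L
    current <- which(!assigned & counts == 0)
    fronts[[level]] <- current
    rank[current] <- level
    assigned[current] <- TRUE
    if (length(current) > 0L) {
      counts <- counts - colSums(dom[current, , drop = FALSE])
    }
    counts[assigned] <- -1L
  }
  list(fronts = fronts, rank = rank)
}

#' Crowding distance within one front
#'
#' Per objective, the front is sorted; boundary members receive `Inf` and
#' interior members accumulate the normalised gap between their neighbours
#' (the cuboid side length). An objective with zero range contributes nothing.
#'
#' @param obj Objective matrix of the front's members.
#' @return Numeric vector of crowding distances (same row order as `obj`).
#' @export
crowding_distance <- function(obj) {
  n <- nrow(obj)
  if (n <= 2L) return(rep(Inf, n))
  d <- numeric(n)
  for (k in seq_len(ncol(obj))) {
    v <- obj[, k]
    ord <- order(v)
    rng <- v[ord[n]] - v[ord[1]]
    if (rng > 0) {  # a zero-range objective contributes nothing
      d[ord[c(1, n)]] <- Inf
      d[ord[2:(n - 1)]] <- d[ord[2:(n - 1)]] +
        (v[ord[3:n]] - v[ord[1:(n - 2)]]) / rng
    }
  }
  d
}

# Crowded-comparison tournament: lower rank wins; equal rank -> larger
# crowding wins; full tie -> seeded coin flip. Returns winning indices.
tournament_select <- function(rank, crowding, n_parents, tournament_size) {
  n <- length(rank)
  winners <- integer(n_parents)
  for (s in seq_len(n_parents)) {
    cand <- sample.int(n, tournament_size, replace = TRUE)
    best <- cand[1]
    for (c in cand[-1]) {
      if (rank[c] < rank[best] ||
          (rank[c] == rank[best] && crowding[c] > crowding[best])) {
        best <- c
      } else if (rank[c] == rank[best] && crowding[c] == crowding[best] &&
                 stats::runif(1) < 0.5) {
        best <- c
      }
    }
    winners[s] <- best
  }
  winners
}

# Vectorised bounded SBX on two parent matrices restricted to one gene column.
# Returns a list of two child vectors.
sbx_gene <- function(p1, p2, lb, ub, eta) {
  eps <- 1e-14
  y1 <- pmin(p1, p2); y2 <- pmax(p1, p2)
  c1 <- p1; c2 <- p2
  act <- (stats::runif(length(p1)) <= 0.5) & (abs(p1 - p2) > eps)
  if (any(act)) {
    u <- stats::runif(sum(act))
    ylo <- y1[act]; yhi <- y2[act]
    dy <- yhi - ylo
    beta <- 1 + 2 * (ylo - lb) / dy
    alpha <- 2 - beta^(-(eta + 1))
    bq1 <- ifelse(u <= 1 / alpha, (u * alpha)^(1 / (eta + 1)),
                  (1 / (2 - u * alpha))^(1 / (eta + 1)))
    ch1 <- 0.5 * ((ylo + yhi) - bq1 * dy)
    beta <- 1 + 2 * (ub - yhi) / dy
    alpha <- 2 - beta^(-(eta + 1))
    bq2 <- ifelse(u <= 1 / alpha, (u * alpha)^(1 / (eta + 1)),
                  (1 / (2 - u * alpha))^(1 / (eta + 1)))
    ch2 <- 0.5 * ((ylo + yhi) + bq2 * dy)
    ch1 <- pmin(pmax(ch1, lb), ub)
    ch2 <- pmin(pmax(ch2, lb), ub)
    swap <- stats::runif(sum(act)) <= 0.5
    c1[act] <- ifelse(swap, ch2, ch1)
    c2[act] <- ifelse(swap, ch1, ch2)
  }
  list(c1, c2)
}

# Vectorised bounded polynomial mutation on one gene column.
poly_mutate_gene <- function(y, lb, ub, eta, p_mut) {
  act <- stats::runif(length(y)) < p_mut
  if (!any(act)) return(y)
  yv <- y[act]
  rng <- ub - lb
  d1 <- (yv - lb) / rng
  d2 <- (ub - yv) / rng
  r <- stats::runif(length(yv))
  mp <- 1 / (eta + 1)
  lower_half <- r < 0.5
  xy <- ifelse(lower_half, 1 - d1, 1 - d2)
  val <- ifelse(lower_half,
                2 * r + (1 - 2 * r) * xy^(eta + 1),
                2 * (1 - r) + 2 * (r - 0.5) * xy^(eta + 1))
  dq <- ifelse(lower_half, val^mp - 1, 1 - val^mp)
  y[act] <- pmin(pmax(yv + dq * rng, lb), ub)
  y
}

#' Produce an offspring population by selection, crossover and mutation
#'
#' Parents are chosen by binary tournament under the crowded-comparison order.
#' Continuous genes recombine by SBX and mutate by polynomial mutation;
#' binary/categorical genes recombine by uniform exchange and mutate by
#' uniform re-draw from their domain. Fixed features are never touched and all
#' offspring are clipped into bounds.
#'
#' @param pop Parent population matrix.
#' @param obj Parent objective matrix.
#' @param rank,crowding Vectors from sorting the parent population.
#' @param config An [nsga2_config()].
#' @param bounds The [resolve_bounds()] tibble.
#' @return Offspring matrix of `config$population_size` rows.
#' @export
make_offspring <- function(pop, obj, rank, crowding, config, bounds) {
  n_off <- config$population_size
  k <- nrow(bounds)
  free <- !bounds$fixed & bounds$lower < bounds$upper
  p_mut <- config$mutation_probability %||% (1 / max(1L, sum(free)))

  parents <- tournament_select(rank, crowding, n_off, config$tournament_size)
  p1 <- pop[parents[seq(1, n_off, by = 2)], , drop = FALSE]
  p2 <- pop[parents[seq(2, n_off, by = 2)], , drop = FALSE]
  n_pairs <- nrow(p1)
  cross <- stats::runif(n_pairs) <= config$crossover_probability

  c1 <- p1; c2 <- p2
  for (j in seq_len(k)) {
    if (!free[j]) next
    lb <- bounds$lower[j]; ub <- bounds$upper[j]
    if (any(cross)) {
      if (bounds$kind[j] == "continuous") {
        ch <- sbx_gene(p1[cross, j], p2[cross, j], lb, ub, config$sbx_eta)
        c1[cross, j] <- ch[[1]]; c2[cross, j] <- ch[[2]]
      } else {
        swap <- stats::runif(sum(cross)) <= 0.5
        a <- p1[cross, j]; b <- p2[cross, j]
        c1[cross, j] <- ifelse(swap, b, a)
        c2[cross, j] <- ifelse(swap, a, b)
      }
    }
    if (bounds$kind[j] == "continuous") {
      c1[, j] <- poly_mutate_gene(c1[, j], lb, ub, config$mutation_eta, p_mut)
      c2[, j] <- poly_mutate_gene(c2[, j], lb, ub, config$mutation_eta, p_mut)
    } else {
      dom <- seq(lb, ub)
      redraw_gene <- function(v) {
        redraw <- stats::runif(length(v)) < p_mut
        if (any(redraw)) v[redraw] <- sample(dom, sum(redraw), replace = TRUE)
        v
      }
      c1[, j] <- redraw_gene(c1[, j])
      c2[, j] <- redraw_gene(c2[, j])
    }
  }
  rbind(c1, c2)
}

#' Elitist environmental selection: top N of parents plus offspring
#'
#' Whole fronts are admitted in rank order until the next front would
#' overflow; that straddling front is truncated by descending crowding
#' distance (ties: members attaining a front-wise objective minimum first,
#' then stable index order).
#'
#' @param pop Combined population matrix (2N rows).
#' @param obj Combined objective matrix.
#' @param n Number of survivors.
#' @return List: `pop`, `obj` (n rows), `rank`, `crowding` for the survivors.
#' @export
environmental_select <- function(pop, obj, n) {
  if (n > nrow(pop)) stop("cannot select more members than supplied", call. = FALSE)
  sorted <- fast_non_dominated_sort(obj)
  keep <- integer(0)
  keep_rank <- integer(0)
  keep_crowd <- numeric(0)
  for (fr in seq_along(sorted$fronts)) {
    idx <- sorted$fronts[[fr]]
    cd <- crowding_distance(obj[idx, , drop = FALSE])
    if (length(keep) + length(idx) <= n) {
      keep <- c(keep, idx)
      keep_rank <- c(keep_rank, rep(fr, length(idx)))
      keep_crowd <- c(keep_crowd, cd)
    } else {
      slots <- n - length(keep)
      # prefer members holding an objective minimum of this front so the
      # per-objective best never regresses between generations
      front_obj <- obj[idx, , drop = FALSE]
      holds_min <- rowSums(front_obj == rep(apply(front_obj, 2, min),
                                            each = length(idx))) > 0
      ord <- order(-cd, !holds_min, seq_along(idx))[seq_len(slots)]
      keep <- c(keep, idx[ord])
      keep_rank <- c(keep_rank, rep(fr, slots))
      keep_crowd <- c(keep_crowd, cd[ord])
      break
    }
  }
  list(pop = pop[keep, , drop = FALSE], obj = obj[keep, , drop = FALSE],
       rank = keep_rank, crowding = keep_crowd)
}

#' Run the elitist multi-objective search for counterfactual genomes
#'
#' The full loop: draw an initial population inside the resolved bounds,
#' evaluate every genome under every disease model, and iterate
#' tournament selection, SBX/uniform crossover, polynomial/uniform mutation,
#' and elitist (rank, crowding) environmental selection over parents plus
#' offspring. Objectives are the per-disease predicted probabilities,
#' minimised simultaneously.
#'
#' @param models List of `risk_model` objects, one per target disease.
#' @param union The [union_features()] search space.
#' @param constraints A [user_constraints()] object.
#' @param config An [nsga2_config()].
#' @param penalty A [penalty_config()] used for the convergence trace and
#'   default ranking; `NULL` builds unit weights in model order.
#' @param window_fraction Passed to [resolve_bounds()].
#' @return An `nsga2_run` object: final `population` and `objectives`
#'   matrices, `front` (row indices of the non-dominated front), `rank`,
#'   `crowding`, a per-generation `trace` tibble (minimum of each objective
#'   and minimum penalty), and the resolved `bounds`, `union`, `config`.
#' @export
run_nsga2 <- function(models, union, constraints = user_constraints(),
                      config = nsga2_config(), penalty = NULL,
                      window_fraction = 0.10) {
  diseases <- purrr::map_chr(models, "disease")
  if (is.null(penalty)) penalty <- penalty_config(disease_order = diseases)
  bounds <- resolve_bounds(union, constraints, window_fraction)
  set.seed(config$seed)
  n <- config$population_size

  pop <- initialize_population(bounds, n)
  obj <- evaluate_population(pop, models, union)
  sorted <- fast_non_dominated_sort(obj)
  rank <- sorted$rank
  crowding <- numeric(n)
  for (idx in sorted$fronts) {
    crowding[idx] <- crowding_distance(obj[idx, , drop = FALSE])
  }

  trace_row <- function(gen, obj) {
    mins <- apply(obj, 2, min)
    pen <- min(penalty_values(obj, penalty))
    tibble::tibble(generation = gen,
                   !!!stats::setNames(as.list(mins), paste0("min_", diseases)),
                   min_penalty = pen)
  }
  trace <- list(trace_row(0L, obj))
  stall <- 0L
  for (gen in seq_len(config$max_generations)) {
    off <- make_offspring(pop, obj, rank, crowding, config, bounds)
    off_obj <- evaluate_population(off, models, union)
    sel <- environmental_select(rbind(pop, off), rbind(obj, off_obj), n)
    pop <- sel$pop; obj <- sel$obj; rank <- sel$rank; crowding <- sel$crowding
    trace[[gen + 1L]] <- trace_row(gen, obj)
    if (!is.null(config$early_stop_generations)) {
      prev <- trace[[gen]]$min_penalty
      stall <- if (trace[[gen + 1L]]$min_penalty < prev) 0L else stall + 1L
      if (stall >= config$early_stop_generations) break
    }
  }
  structure(list(population = pop, objectives = obj,
                 front = which(rank == 1L), rank = rank, crowding = crowding,
                 trace = dplyr::bind_rows(trace), diseases = diseases,
                 bounds = bounds, union = union, config = config,
                 penalty = penalty),
            class = "nsga2_run")
}

#' @export
print.nsga2_run <- function(x, ...) {
  cat("<nsga2_run> ", length(x$diseases), " objectives (",
      paste(x$diseases, collapse = ", "), "), population ",
      x$config$population_size, ", ",
      max(x$trace$generation), " generations\n", sep = "")
  cat("  Pareto front: ", length(x$front), " members; objective minima: ",
      paste(signif(apply(x$objectives, 2, min), 4), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the final Pareto front of a run
#'
#' @param x An `nsga2_run`.
#' @param ... Unused.
#' @return Tibble: one row per front member, columns `.member`, the
#'   per-disease probabilities (`prob_<disease>`), `penalty`, and the decoded
#'   feature values.
#' @export
tidy.nsga2_run <- function(x, ...) {
  idx <- x$front
  probs <- x$objectives[idx, , drop = FALSE]
  colnames(probs) <- paste0("prob_", x$diseases)
  raw <- decode_population(x$population[idx, , drop = FALSE], x$union)
  dplyr::bind_cols(
    tibble::tibble(.member = idx),
    tibble::as_tibble(probs),
    tibble::tibble(penalty = penalty_values(x$objectives[idx, , drop = FALSE],
                                            x$penalty)),
    raw)
}

#' One-row summary of a run
#'
#' @param x An `nsga2_run`.
#' @param ... Unused.
#' @return One-row tibble: population size, generations executed, front size,
#'   per-objective minima and minimum penalty.
#' @export
glance.nsga2_run <- function(x, ...) {
  mins <- apply(x$objectives, 2, min)
  tibble::tibble(population_size = x$config$population_size,
                 generations = max(x$trace$generation),
                 front_size = length(x$front),
                 !!!stats::setNames(as.list(mins), paste0("min_", x$diseases)),
                 min_penalty = min(penalty_values(x$objectives, x$penalty)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
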