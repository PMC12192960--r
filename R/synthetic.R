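#' Default two-disease synthetic problem specification
#'
#' Mirrors the structure of the public stroke and diabetes tables the package
#' is designed around: a 15-feature union in which the stroke model sees 10
#' features and the diabetes model 8, with exactly three shared continuous
#' features (age, average glucose level, BMI), plus binary and multi-category
#' columns. Default bounds are clinically plausible ranges.
#'
#' @return List with `registry` (a [feature_registry()]), `sets` (list of
#'   [disease_features()]), and `union`.
#' @export
default_problem_spec <- function() {
  registry <- feature_registry(
    feature_spec("age", "continuous", 18, 100),
    feature_spec("hypertension", "binary"),
    feature_spec("heart_disease", "binary"),
    feature_spec("avg_glucose_level", "continuous", 55, 300),
    feature_spec("bmi", "continuous", 10, 60),
    feature_spec("gender", "binary", labels = c("female", "male")),
    feature_spec("ever_married", "binary"),
    feature_spec("work_type", "categorical",
                 categories = c("Private", "Self-employed", "Govt_job",
                                "children", "Never_worked")),
    feature_spec("residence_type", "binary", labels = c("rural", "urban")),
    feature_spec("smoking_status", "categorical",
                 categories = c("never smoked", "formerly smoked", "smokes",
                                "Unknown")),
    feature_spec("pregnancies", "continuous", 0, 17),
    feature_spec("blood_pressure", "continuous", 40, 130),
    feature_spec("skin_thickness", "continuous", 0, 99),
    feature_spec("insulin", "continuous", 0, 850),
    feature_spec("diabetes_pedigree_function", "continuous", 0.05, 2.5))
  sets <- list(
    disease_features("stroke",
                     c("age", "hypertension", "heart_disease",
                       "avg_glucose_level", "bmi", "gender", "ever_married",
                       "work_type", "residence_type", "smoking_status")),
    disease_features("diabetes",
                     c("pregnancies", "avg_glucose_level", "blood_pressure",
                       "skin_thickness", "insulin", "bmi",
                       "diabetes_pedigree_function", "age")))
  list(registry = registry, sets = sets,
       union = union_features(sets, registry))
}

# Linear predictor of a logistic ground truth on raw feature rows.
# Continuous features act through their position in the default bounds
# (z = (x - lower) / (upper - lower)); binary through 0/1; categorical
# through a per-level effect.
truth_linpred <- function(truth, registry, raw) {
  lp <- rep(truth$intercept, nrow(raw))
  for (f in names(truth$effects)) {
    row <- registry[registry$feature == f, ]
    eff <- truth$effects[[f]]
    lp <- lp + switch(row$kind,
      continuous = eff * (raw[[f]] - row$lower) / (row$upper - row$lower),
      binary = eff * as.numeric(raw[[f]]),
      categorical = eff[match(as.character(raw[[f]]), row$categories[[1]])])
  }
  lp
}

#' Generate a multi-disease synthetic problem with logistic ground truth
#'
#' One master subject table is drawn over the unioned feature space
#' (continuous features uniform in their default bounds, binary and
#' categorical uniform over their domains) and projected onto each disease's
#' feature subset, so shared features carry identical values for the same
#' subject. Each disease's binary outcome is Bernoulli under a known logistic
#' risk surface whose coefficients act on bound-normalised feature values; the
#' intercept is centred so that zero coefficients give prevalence 1/2.
#'
#' @param n_subjects Number of rows (>= 10).
#' @param spec A [default_problem_spec()]-shaped list (registry, sets, union).
#' @param coef_range Coefficient magnitudes are drawn uniformly in this range
#'   (default \[-2, 2\], spanning probabilities non-degenerately).
#' @param seed Integer seed; the whole problem is reproducible from it.
#' @param intercept_shift Added to each centred intercept (default 0).
#' @param null_fraction Optional fraction of continuous cells set to `NA`
#'   (for exercising median imputation; default 0).
#' @return A `synthetic_problem`: `tables` (named list of per-disease tibbles
#'   with an `outcome` column), `truth` (per-disease intercept + effects),
#'   `registry`, `sets`, `union`, `seed`.
#' @export
generate_problem <- function(n_subjects, spec = default_problem_spec(),
                             coef_range = c(-2, 2), seed = 1L,
                             intercept_shift = 0, null_fraction = 0) {
  if (n_subjects < 10L) stop("n_subjects must be >= 10", call. = FALSE)
  registry <- spec$registry; union <- spec$union
  if (any(purrr::map_int(spec$sets, ~ length(.x$features)) == 0L)) {
    stop("every disease needs a non-empty feature set", call. = FALSE)
  }
  set.seed(seed)

  master <- purrr::map(seq_len(nrow(union$features)), function(i) {
    row <- union$features[i, ]
    switch(row$kind,
      continuous = stats::runif(n_subjects, row$lower, row$upper),
      binary = sample(0:1, n_subjects, replace = TRUE),
      categorical = sample(row$categories[[1]], n_subjects, replace = TRUE))
  })
  names(master) <- union$features$feature
  master <- tibble::as_tibble(master)

  truth <- purrr::map(spec$sets, function(s) {
    effects <- purrr::map(s$features, function(f) {
      row <- registry[registry$feature == f, ]
      n_eff <- if (row$kind == "categorical") length(row$categories[[1]]) else 1L
      stats::runif(n_eff, coef_range[1], coef_range[2])
    })
    names(effects) <- s$features
    # centre so the expected linear predictor over the uniform prior is ~0
    mean_eff <- sum(purrr::map_dbl(effects, mean)) -
      sum(purrr::map_dbl(effects, ~ if (length(.x) == 1L) mean(.x) / 2 else 0))
    list(disease = s$disease, intercept = -mean_eff + intercept_shift,
         effects = effects)
  })
  names(truth) <- purrr::map_chr(spec$sets, "disease")

  tables <- purrr::map(spec$sets, function(s) {
    tab <- master[, s$features, drop = FALSE]
    p <- stats::plogis(truth_linpred(truth[[s$disease]], registry, tab))
    tab$outcome <- stats::rbinom(n_subjects, 1L, p)
    if (null_fraction > 0) {
      for (f in s$features) {
        if (registry$kind[registry$feature == f] == "continuous") {
          hit <- stats::runif(n_subjects) < null_fraction
          tab[[f]][hit] <- NA_real_
        }
      }
    }
    tab
  })
  names(tables) <- names(truth)

  structure(list(tables = tables, truth = truth, registry = registry,
                 sets = spec$sets, union = union, seed = as.integer(seed)),
            class = "synthetic_problem")
}

#' @export
print.synthetic_problem <- function(x, ...) {
  cat("<synthetic_problem> ", length(x$tables), " disease(s), ",
      nrow(x$tables[[1]]), " subjects, ", nrow(x$union$features),
      "-feature union\n", sep = "")
  invisible(x)
}

#' Wrap a problem's ground-truth risk surfaces as risk models
#'
#' @param problem A [generate_problem()] result.
#' @return Named list of `risk_model` objects evaluating the true logistic
#'   risks (useful as exactly-known oracles for the optimiser).
#' @export
make_truth_models <- function(problem) {
  out <- purrr::map(names(problem$truth), function(d) {
    tr <- problem$truth[[d]]
    make_risk_model(d, names(tr$effects), function(raw) {
      stats::plogis(truth_linpred(tr, problem$registry, raw))
    }, label = "ground_truth")
  })
  names(out) <- names(problem$truth)
  out
}

#' Analytic box-constrained minimiser of one disease's true risk
#'
#' A logistic risk surface is monotone in each coordinate, so within a box
#' each free continuous/binary feature sits at the bound opposite its
#' coefficient sign (positive coefficient -> lower bound) and each free
#' categorical feature at its minimum-effect category; fixed features stay at
#' their constants. Ties take the lower bound / first category.
#'
#' @param truth One disease's entry of `problem$truth`.
#' @param bounds A [resolve_bounds()] tibble covering the truth's features.
#' @param registry The problem's feature registry.
#' @return List: `genome` (named encoded optimum over the truth's features)
#'   and `probability` (the minimum achievable true risk).
#' @export
analytic_optimum <- function(truth, bounds, registry) {
  genome <- purrr::map_dbl(names(truth$effects), function(f) {
    b <- bounds[bounds$feature == f, ]
    eff <- truth$effects[[f]]
    if (b$fixed || b$lower == b$upper) return(b$lower)
    switch(b$kind,
      continuous = if (eff[1] > 0) b$lower else b$upper,
      binary = if (eff[1] > 0) 0 else 1,
      categorical = {
        allowed <- seq(b$lower, b$upper)
        allowed[which.min(eff[allowed])]
      })
  })
  names(genome) <- names(truth$effects)
  raw <- decode_matrix(matrix(genome, nrow = 1,
                              dimnames = list(NULL, names(genome))),
                       registry[match(names(genome), registry$feature), ])
  p <- stats::plogis(truth_linpred(truth, registry, raw))
  list(genome = genome, probability = as.numeric(p))
}

# Non-dominated filter for two-objective minimisation, implemented by a
# sort-and-scan sweep (independent of the optimiser's sorting code).
nondominated_2d <- function(p1, p2) {
  n <- length(p1)
  keep <- rep(FALSE, n)
  ord <- order(p1, p2)
  best2 <- Inf
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && p1[ord[j + 1L]] == p1[ord[i]]) j <- j + 1L
    grp <- ord[i:j]
    gmin <- min(p2[grp])
    if (gmin < best2) keep[grp[p2[grp] == gmin]] <- TRUE
    best2 <- min(best2, gmin)
    i <- j + 1L
  }
  keep
}

#' Exact sampled Pareto front of a two-disease logistic ground truth
#'
#' Features exclusive to one disease cannot trade off against the other, so
#' they are pinned at that disease's analytic optimum; the front is traced by
#' the shared free features, which are grid-enumerated over the resolved box
#' (continuous features at `grid_resolution` points, discrete features over
#' their full domain). The non-dominated subset is extracted with a
#' brute-force dominance sweep independent of the optimiser's code.
#'
#' @param problem A two-disease [generate_problem()] result.
#' @param bounds A [resolve_bounds()] tibble for the problem's union.
#' @param grid_resolution Points per shared continuous feature (default 33).
#' @return Tibble of non-dominated rows: one probability column per disease
#'   plus the shared-feature values tracing the front.
#' @export
analytic_pareto <- function(problem, bounds, grid_resolution = 33L) {
  diseases <- names(problem$truth)
  if (length(diseases) != 2L) {
    stop("analytic_pareto needs exactly two diseases", call. = FALSE)
  }
  shared <- intersect(names(problem$truth[[1]]$effects),
                      names(problem$truth[[2]]$effects))
  if (length(shared) == 0L) stop("no shared features", call. = FALSE)

  axes <- purrr::map(shared, function(f) {
    b <- bounds[bounds$feature == f, ]
    if (b$fixed || b$lower == b$upper) return(b$lower)
    if (b$kind == "continuous") {
      seq(b$lower, b$upper, length.out = grid_resolution)
    } else {
      seq(b$lower, b$upper)
    }
  })
  names(axes) <- shared
  n_points <- prod(purrr::map_dbl(axes, length))
  if (n_points > 1e6) {
    stop("shared-feature grid has ", format(n_points, big.mark = ","),
         " points (> 1e6); use a coarser grid_resolution", call. = FALSE)
  }
  grid <- do.call(expand.grid, c(axes, KEEP.OUT.ATTRS = FALSE))

  probs <- purrr::map(diseases, function(d) {
    tr <- problem$truth[[d]]
    own <- setdiff(names(tr$effects), shared)
    opt <- analytic_optimum(tr, bounds, problem$registry)
    full <- matrix(rep(opt$genome[names(tr$effects)], each = nrow(grid)),
                   nrow = nrow(grid),
                   dimnames = list(NULL, names(tr$effects)))
    for (f in intersect(shared, names(tr$effects))) full[, f] <- grid[[f]]
    raw <- decode_matrix(full, problem$registry[match(names(tr$effects),
                                                      problem$registry$feature), ])
    as.numeric(stats::plogis(truth_linpred(tr, problem$registry, raw)))
  })
  keep <- nondominated_2d(probs[[1]], probs[[2]])
  out <- tibble::tibble(!!paste0("prob_", diseases[1]) := probs[[1]][keep],
                        !!paste0("prob_", diseases[2]) := probs[[2]][keep])
  dplyr::bind_cols(out, tibble::as_tibble(grid[keep, , drop = FALSE]))
}
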