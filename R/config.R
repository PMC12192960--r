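#' Read a problem configuration file (YAML or JSON)
#'
#' The file declares the target diseases, the feature registry, per-disease
#' membership, user constraints, and optional optimiser/penalty sections:
#'
#' ```yaml
#' diseases: [stroke, diabetes]
#' features:
#'   age: {kind: continuous, default_bounds: [18, 100]}
#'   work_type: {kind: categorical, categories: [Private, Govt_job]}
#'   hypertension: {kind: binary}
#' membership:
#'   stroke: [age, hypertension]
#'   diabetes: [age]
#' constraints:
#'   fixed: {age: 32}
#'   windows: {bmi: [22, 30]}
#'   anchors: {avg_glucose_level: 100}
#' optimizer: {population_size: 100, max_generations: 40, seed: 1}
#' penalty: {lambda: 1}
#' outcome: outcome
#' n_cf: 2
#' ```
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return List: `diseases`, `registry`, `sets`, `union`, `constraints`,
#'   `optimizer` (an [nsga2_config()]), `penalty` (a [penalty_config()]),
#'   `outcome`, `n_cf`.
#' @export
read_problem_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  for (key in c("diseases", "features", "membership")) {
    if (is.null(raw[[key]])) {
      stop("config is missing required section '", key, "'", call. = FALSE)
    }
  }
  registry <- feature_registry(dplyr::bind_rows(
    purrr::imap(raw$features, function(f, name) {
      feature_spec(name, kind = f$kind,
                   lower = f$default_bounds[1], upper = f$default_bounds[2],
                   categories = f$categories, labels = f$labels)
    })))
  sets <- purrr::map(raw$diseases, function(d) {
    if (is.null(raw$membership[[d]])) {
      stop("no membership listed for disease '", d, "'", call. = FALSE)
    }
    disease_features(d, unlist(raw$membership[[d]]))
  })
  cons <- raw$constraints %||% list()
  constraints <- user_constraints(
    fixed = cons$fixed %||% list(),
    windows = purrr::map(cons$windows %||% list(), unlist),
    anchors = cons$anchors %||% list())
  optimizer <- do.call(nsga2_config, raw$optimizer %||% list())
  pen <- raw$penalty %||% list()
  penalty <- penalty_config(weights = pen$weights,
                            lambda = pen$lambda %||% 1,
                            disease_order = unlist(raw$diseases))
  list(diseases = unlist(raw$diseases), registry = registry, sets = sets,
       union = union_features(sets, registry), constraints = constraints,
       optimizer = optimizer, penalty = penalty,
       outcome = raw$outcome %||% "outcome", n_cf = raw$n_cf %||% 2L)
}

#' Write the default synthetic problem spec as a config file
#'
#' @param path Destination (`.yaml` or `.json`).
#' @param spec A [default_problem_spec()]-shaped list.
#' @param constraints Optional [user_constraints()] to embed.
#' @param optimizer Optional [nsga2_config()] to embed.
#' @return `path`, invisibly.
#' @export
write_problem_config <- function(path, spec = default_problem_spec(),
                                 constraints = NULL, optimizer = NULL) {
  reg <- spec$registry
  features <- purrr::map(seq_len(nrow(reg)), function(i) {
    row <- reg[i, ]
    out <- list(kind = row$kind)
    if (row$kind == "continuous") out$default_bounds <- c(row$lower, row$upper)
    if (row$kind == "categorical") out$categories <- row$categories[[1]]
    if (row$kind == "binary") out$labels <- row$labels[[1]]
    out
  })
  names(features) <- reg$feature
  cfg <- list(
    diseases = purrr::map_chr(spec$sets, "disease"),
    features = features,
    membership = stats::setNames(purrr::map(spec$sets, "features"),
                                 purrr::map_chr(spec$sets, "disease")))
  if (!is.null(constraints)) {
    cfg$constraints <- list(fixed = constraints$fixed,
                            windows = constraints$windows,
                            anchors = constraints$anchors)
  }
  if (!is.null(optimizer)) {
    cfg$optimizer <- optimizer[c("population_size", "max_generations",
                                 "crossover_probability", "sbx_eta",
                                 "mutation_eta", "tournament_size", "seed")]
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}
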