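#' Penalty configuration for ranking Pareto solutions
#'
#' The scalar penalty collapses the per-disease probability vector into one
#' score used to rank the final Pareto front. For two diseases it is
#' `w1 * P1 + w2 * P2 + lambda * max(0, P1 - P2)` with the diseases taken in
#' `disease_order` (the asymmetric gap term penalises solutions that leave the
#' first-listed disease riskier than the second). For n > 2 diseases the gap
#' term generalises to the sum of positive ordered pairwise gaps
#' `sum_{i<j} max(0, P_i - P_j)`, which reduces exactly to the two-disease
#' form; this generalisation is this package's documented extension.
#'
#' @param weights Per-disease weights (default all 1).
#' @param lambda Non-negative gap-penalty coefficient (default 1).
#' @param disease_order Ordered disease identifiers; required because the gap
#'   term is asymmetric.
#' @return A `penalty_config` object.
#' @export
penalty_config <- function(weights = NULL, lambda = 1, disease_order) {
  if (missing(disease_order) || length(disease_order) < 1L) {
    stop("disease_order is required (the gap term is asymmetric)", call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, length(disease_order))
  if (length(weights) != length(disease_order)) {
    stop("weights must have one entry per disease", call. = FALSE)
  }
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  structure(list(weights = as.numeric(weights), lambda = as.numeric(lambda),
                 disease_order = as.character(disease_order)),
            class = "penalty_config")
}

#' Penalty of one probability vector
#'
#' @param probabilities Per-disease probabilities, in `config$disease_order`
#'   (or named, in which case they are reordered by name).
#' @param config A [penalty_config()].
#' @return Numeric scalar.
#' @export
#' @examples
#' cfg <- penalty_config(disease_order = c("stroke", "diabetes"))
#' penalty(c(0.00001095, 0.00025517), cfg)  # 0.00026612
penalty <- function(probabilities, config) {
  stopifnot(inherits(config, "penalty_config"))
  if (length(probabilities) != length(config$weights)) {
    stop("probability vector length does not match the number of diseases",
         call. = FALSE)
  }
  if (!is.null(names(probabilities)) &&
      all(config$disease_order %in% names(probabilities))) {
    probabilities <- probabilities[config$disease_order]
  }
  p <- as.numeric(probabilities)
  gap <- 0
  n <- length(p)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      gap <- gap + sum(pmax(0, p[i] - p[(i + 1L):n]))
    }
  }
  sum(config$weights * p) + config$lambda * gap
}

# Vectorised penalty over an objective matrix (columns named by disease when
# available; otherwise assumed already in disease order).
penalty_values <- function(obj, config) {
  if (!is.null(colnames(obj)) && all(config$disease_order %in% colnames(obj))) {
    obj <- obj[, config$disease_order, drop = FALSE]
  }
  apply(obj, 1, penalty, config = config)
}

#' Rank the Pareto front and keep the requested number of counterfactuals
#'
#' Front members are sorted by ascending penalty (ties: larger crowding
#' distance, then stable member order) and numbered CF 1, CF 2, ... A warning
#' is raised when the front holds fewer members than requested.
#'
#' @param run An `nsga2_run`.
#' @param n_cf Positive number of counterfactuals wanted.
#' @param config A [penalty_config()]; defaults to the run's own.
#' @return A `counterfactual_set`: tibble with `cf`, per-disease `prob_*`
#'   columns, `penalty`, `crowding` and the decoded feature values, carrying
#'   the run's union and bounds as attributes.
#' @export
select_counterfactuals <- function(run, n_cf, config = run$penalty) {
  stopifnot(inherits(run, "nsga2_run"))
  if (n_cf < 1L) stop("n_cf must be >= 1", call. = FALSE)
  idx <- run$front
  if (length(idx) < n_cf) {
    warning("Pareto front has only ", length(idx), " member(s); returning ",
            length(idx), " counterfactual(s) instead of ", n_cf, call. = FALSE)
  }
  pen <- penalty_values(run$objectives[idx, , drop = FALSE], config)
  ord <- order(pen, -run$crowding[idx], seq_along(idx))
  take <- ord[seq_len(min(n_cf, length(idx)))]
  probs <- run$objectives[idx[take], , drop = FALSE]
  colnames(probs) <- paste0("prob_", run$diseases)
  out <- dplyr::bind_cols(
    tibble::tibble(cf = seq_along(take)),
    tibble::as_tibble(probs),
    tibble::tibble(penalty = pen[take], crowding = run$crowding[idx[take]]),
    decode_population(run$population[idx[take], , drop = FALSE], run$union))
  structure(out, class = c("counterfactual_set", class(out)),
            union = run$union, bounds = run$bounds,
            genomes = run$population[idx[take], , drop = FALSE])
}

#' Render counterfactuals as a user-facing recommendation table
#'
#' One row per feature of the unioned search space (genome order), one column
#' per counterfactual. Fixed features display their constants; binary and
#' categorical genes are rendered as labels ("yes", "Private", ...);
#' continuous values are rounded to `digits` decimals.
#'
#' @param cfs A [select_counterfactuals()] result.
#' @param digits Decimals for continuous features (default 3).
#' @return Tibble: `feature`, then `CF_1`, `CF_2`, ... character columns.
#' @export
cf_report <- function(cfs, digits = 3) {
  stopifnot(inherits(cfs, "counterfactual_set"), nrow(cfs) >= 1L)
  union <- attr(cfs, "union")
  genomes <- attr(cfs, "genomes")
  cols <- purrr::map(seq_len(nrow(genomes)), function(i) {
    purrr::map_chr(seq_len(nrow(union$features)), function(j) {
      render_gene(union$features[j, ], genomes[i, union$features$feature[j]],
                  digits)
    })
  })
  names(cols) <- paste0("CF_", cfs$cf)
  dplyr::bind_cols(tibble::tibble(feature = union$features$feature),
                   tibble::as_tibble(cols))
}

#' Export the Pareto front as an objective-pair table
#'
#' @param run An `nsga2_run`.
#' @param config A [penalty_config()]; defaults to the run's own.
#' @return Tibble: per-disease probability columns, `penalty`, and `is_best`
#'   flagging the minimum-penalty member (the plotted "optimal solution").
#' @export
pareto_export <- function(run, config = run$penalty) {
  stopifnot(inherits(run, "nsga2_run"))
  probs <- run$objectives[run$front, , drop = FALSE]
  pen <- penalty_values(probs, config)
  colnames(probs) <- run$diseases
  out <- dplyr::bind_cols(tibble::as_tibble(probs),
                          tibble::tibble(penalty = pen))
  out$is_best <- seq_len(nrow(out)) == which.min(pen)
  out
}
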