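#' Declare a single feature of the search space
#'
#' A feature is one axis of the unioned search space over which counterfactual
#' recommendations are generated. Continuous features carry default box bounds,
#' binary features live on \{0, 1\} (with optional display labels such as
#' "no"/"yes"), and categorical features carry an ordered set of labels that
#' are label-encoded as integer gene indices during optimisation.
#'
#' @param name Feature identifier (column name in the disease tables).
#' @param kind One of `"continuous"`, `"binary"`, `"categorical"`.
#' @param lower,upper Default bounds (continuous only).
#' @param categories Ordered character vector of category labels
#'   (categorical only); must be non-empty and unique.
#' @param labels Optional length-2 character vector rendering a binary
#'   feature's 0/1 values in reports (default `c("no", "yes")`).
#'
#' @return A one-row tibble (a feature-registry row).
#' @export
#' @examples
#' feature_spec("bmi", "continuous", lower = 10, upper = 60)
#' feature_spec("smoking_status", "categorical",
#'              categories = c("never smoked", "formerly smoked", "smokes"))
feature_spec <- function(name, kind = c("continuous", "binary", "categorical"),
                         lower = NULL, upper = NULL, categories = NULL,
                         labels = NULL) {
  kind <- match.arg(kind)
  if (kind == "continuous") {
    if (is.null(lower) || is.null(upper)) {
      stop("continuous feature '", name, "' needs default `lower` and `upper` bounds",
           call. = FALSE)
    }
    if (lower > upper) {
      stop("feature '", name, "': lower bound exceeds upper bound", call. = FALSE)
    }
  }
  if (kind == "categorical") {
    if (is.null(categories) || length(categories) == 0L ||
        anyDuplicated(categories)) {
      stop("categorical feature '", name,
           "' needs a non-empty set of unique category labels", call. = FALSE)
    }
  }
  if (kind == "binary" && is.null(labels)) labels <- c("no", "yes")
  tibble::tibble(
    feature = as.character(name),
    kind = kind,
    lower = if (kind == "continuous") as.numeric(lower) else NA_real_,
    upper = if (kind == "continuous") as.numeric(upper) else NA_real_,
    categories = list(if (kind == "categorical") as.character(categories) else NULL),
    labels = list(if (kind == "binary") as.character(labels) else NULL)
  )
}

#' Build a feature registry from individual feature specs
#'
#' @param ... One-row tibbles from [feature_spec()], or a single tibble of them.
#' @return A `feature_registry` tibble, one row per feature.
#' @export
feature_registry <- function(...) {
  rows <- list(...)
  if (length(rows) == 1L && is.data.frame(rows[[1]]) && nrow(rows[[1]]) > 1L) {
    reg <- rows[[1]]
  } else {
    reg <- dplyr::bind_rows(rows)
  }
  if (anyDuplicated(reg$feature)) {
    stop("duplicate feature names in registry: ",
         paste(unique(reg$feature[duplicated(reg$feature)]), collapse = ", "),
         call. = FALSE)
  }
  class(reg) <- c("feature_registry", class(reg))
  reg
}

#' Declare the feature set of one disease model
#'
#' @param disease Disease identifier.
#' @param features Ordered character vector of feature names (the model's
#'   training column order); must be unique.
#' @return A `disease_features` object.
#' @export
disease_features <- function(disease, features) {
  features <- as.character(features)
  if (anyDuplicated(features)) {
    stop("duplicate feature names for disease '", disease, "'", call. = FALSE)
  }
  structure(list(disease = as.character(disease), features = features),
            class = "disease_features")
}

#' Union the feature sets of several diseases
#'
#' Counterfactual search happens over the union of all per-disease feature
#' sets: features shared between diseases appear once, and each disease keeps
#' a membership map back to exactly its own features. Order is
#' first-appearance order across the disease list, which fixes the genome
#' layout deterministically.
#'
#' @param sets List of [disease_features()] objects.
#' @param registry A [feature_registry()] resolving every referenced name.
#' @return A `feature_union` object with elements `features` (registry rows in
#'   union order) and `membership` (named list: disease -> feature names).
#' @export
#' @examples
#' reg <- feature_registry(
#'   feature_spec("a", "continuous", 0, 1),
#'   feature_spec("b", "continuous", 0, 1),
#'   feature_spec("c", "binary"))
#' u <- union_features(list(disease_features("d1", c("a", "b")),
#'                          disease_features("d2", c("b", "c"))), reg)
#' u$features$feature   # "a" "b" "c"
union_features <- function(sets, registry) {
  stopifnot(length(sets) >= 1L)
  for (s in sets) {
    missing <- setdiff(s$features, registry$feature)
    if (length(missing) > 0L) {
      stop("disease '", s$disease, "' references unknown feature(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  ordered <- unique(unlist(purrr::map(sets, "features")))
  features <- registry[match(ordered, registry$feature), , drop = FALSE]
  membership <- purrr::map(sets, "features")
  names(membership) <- purrr::map_chr(sets, "disease")
  structure(list(features = tibble::as_tibble(features), membership = membership),
            class = "feature_union")
}

#' @export
print.feature_union <- function(x, ...) {
  cat("<feature_union> ", nrow(x$features), " features, ",
      length(x$membership), " disease(s)\n", sep = "")
  for (d in names(x$membership)) {
    cat("  ", d, ": ", paste(x$membership[[d]], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Features common to every disease
#'
#' @param sets List of at least two [disease_features()] objects.
#' @return Character vector of shared feature names, in the first set's order.
#' @export
intersect_features <- function(sets) {
  if (length(sets) < 2L) {
    stop("intersect_features() needs at least two feature sets", call. = FALSE)
  }
  Reduce(intersect, purrr::map(sets, "features"))
}

#' User constraints: immutable features, value windows, anchors
#'
#' Users mark features they cannot change (`fixed`, e.g. age or gender) and
#' optionally restrict changeable continuous features either with an explicit
#' `window` or with an `anchor` value from which a default +/-10 percent
#' window is derived by [resolve_bounds()].
#'
#' @param fixed Named list: feature -> constant value. Categorical constants
#'   may be given as labels; binary constants as 0/1 or their display labels.
#' @param windows Named list: feature -> numeric `c(lower, upper)`.
#' @param anchors Named list: feature -> the user's current value (continuous
#'   features only).
#' @return A `user_constraints` object.
#' @export
user_constraints <- function(fixed = list(), windows = list(), anchors = list()) {
  overlap <- intersect(names(fixed), names(windows))
  if (length(overlap) > 0L) {
    stop("feature(s) both fixed and windowed: ", paste(overlap, collapse = ", "),
         call. = FALSE)
  }
  for (f in names(windows)) {
    w <- windows[[f]]
    if (length(w) != 2L || !is.numeric(w) || w[1] > w[2]) {
      stop("window for '", f, "' must be numeric c(lower, upper) with lower <= upper",
           call. = FALSE)
    }
  }
  structure(list(fixed = fixed, windows = windows, anchors = anchors),
            class = "user_constraints")
}

# Encode a user-supplied constant into its gene value (categorical -> index,
# binary label -> 0/1), validating domain membership.
encode_constant <- function(row, value) {
  feature <- row$feature
  kind <- row$kind
  if (kind == "continuous") {
    v <- as.numeric(value)
    if (is.na(v) || v < row$lower || v > row$upper) {
      stop("fixed value ", value, " for '", feature,
           "' lies outside its default bounds [", row$lower, ", ", row$upper, "]",
           call. = FALSE)
    }
    return(v)
  }
  if (kind == "binary") {
    labels <- row$labels[[1]]
    if (is.character(value)) {
      i <- match(value, labels)
      if (is.na(i)) {
        stop("fixed value '", value, "' for binary '", feature,
             "' is not one of: ", paste(labels, collapse = ", "), call. = FALSE)
      }
      return(i - 1)
    }
    v <- as.numeric(value)
    if (!v %in% c(0, 1)) {
      stop("fixed value for binary '", feature, "' must be 0 or 1", call. = FALSE)
    }
    return(v)
  }
  # categorical
  cats <- row$categories[[1]]
  if (is.character(value)) {
    i <- match(value, cats)
    if (is.na(i)) {
      stop("fixed value '", value, "' for '", feature,
           "' is not a known category", call. = FALSE)
    }
    return(i)
  }
  v <- as.integer(value)
  if (is.na(v) || v < 1L || v > length(cats)) {
    stop("fixed category index for '", feature, "' out of range", call. = FALSE)
  }
  as.numeric(v)
}

#' Resolve the per-feature box constraints for the genetic search
#'
#' Applies, in priority order: fixed constants (degenerate intervals), explicit
#' user windows (clipped to default bounds), anchor-derived windows
#' (`anchor * (1 - window_fraction)` to `anchor * (1 + window_fraction)`,
#' clipped to defaults), and finally the default bounds. Binary and
#' categorical features without a fixed value keep their full domain, encoded
#' as integer gene ranges (0..1 and 1..n_categories).
#'
#' @param union A [union_features()] result.
#' @param constraints A [user_constraints()] object.
#' @param window_fraction Half-width of the anchor-derived relative window
#'   (default 0.10, i.e. +/-10 percent of the anchored value).
#' @return A tibble with columns `feature`, `kind`, `lower`, `upper`, `fixed`.
#'   For fixed features `lower == upper` equals the (encoded) constant.
#' @export
#' @examples
#' reg <- feature_registry(feature_spec("glucose", "continuous", 0, 1000))
#' u <- union_features(list(disease_features("d", "glucose")), reg)
#' resolve_bounds(u, user_constraints(anchors = list(glucose = 100)))
#' # -> window [90, 110]
resolve_bounds <- function(union, constraints = user_constraints(),
                           window_fraction = 0.10) {
  stopifnot(inherits(union, "feature_union"))
  if (!inherits(constraints, "user_constraints")) {
    stop("`constraints` must be a user_constraints object", call. = FALSE)
  }
  unknown <- setdiff(
    unique(c(names(constraints$fixed), names(constraints$windows),
             names(constraints$anchors))),
    union$features$feature)
  if (length(unknown) > 0L) {
    stop("constraints reference unknown feature(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  rows <- purrr::map(seq_len(nrow(union$features)), function(i) {
    row <- union$features[i, ]
    f <- row$feature
    dom <- switch(row$kind,
      continuous  = c(row$lower, row$upper),
      binary      = c(0, 1),
      categorical = c(1, length(row$categories[[1]])))

    if (f %in% names(constraints$fixed)) {
      v <- encode_constant(row, constraints$fixed[[f]])
      return(tibble::tibble(feature = f, kind = row$kind,
                            lower = v, upper = v, fixed = TRUE))
    }
    lo <- dom[1]; hi <- dom[2]
    if (f %in% names(constraints$windows)) {
      if (row$kind != "continuous") {
        stop("value window on non-continuous feature '", f, "'", call. = FALSE)
      }
      w <- constraints$windows[[f]]
      if (w[2] < dom[1] || w[1] > dom[2]) {
        stop("window [", w[1], ", ", w[2], "] for '", f,
             "' lies entirely outside default bounds [", dom[1], ", ", dom[2], "]",
             call. = FALSE)
      }
      lo <- max(w[1], dom[1]); hi <- min(w[2], dom[2])
    } else if (f %in% names(constraints$anchors)) {
      if (row$kind != "continuous") {
        stop("anchor value supplied for non-continuous feature '", f, "'",
             call. = FALSE)
      }
      v <- as.numeric(constraints$anchors[[f]])
      w <- sort(c(v * (1 - window_fraction), v * (1 + window_fraction)))
      lo <- max(w[1], dom[1]); hi <- min(w[2], dom[2])
      if (hi < lo) { # anchor outside defaults: collapse onto nearest bound
        lo <- hi <- if (v < dom[1]) dom[1] else dom[2]
      }
    }
    tibble::tibble(feature = f, kind = row$kind, lower = lo, upper = hi,
                   fixed = FALSE)
  })
  dplyr::bind_rows(rows)
}

#' Project a full assignment onto one disease's feature vector
#'
#' @param assignment Named list or vector covering every feature of the union.
#' @param union A [union_features()] result.
#' @param disease Disease identifier present in the union's membership.
#' @return Named vector/list of the disease's feature values, in that model's
#'   training column order. Features outside the disease's set are ignored.
#' @export
project <- function(assignment, union, disease) {
  if (!disease %in% names(union$membership)) {
    stop("unknown disease '", disease, "'", call. = FALSE)
  }
  missing <- setdiff(union$features$feature, names(assignment))
  if (length(missing) > 0L) {
    stop("assignment is missing feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  assignment[union$membership[[disease]]]
}

# Decode an encoded matrix (categorical genes as integer indices) into a raw
# tibble with label-valued categorical columns, guided by registry rows.
decode_matrix <- function(pop, features_tbl) {
  stopifnot(is.matrix(pop))
  cols <- purrr::map(seq_len(nrow(features_tbl)), function(i) {
    row <- features_tbl[i, ]
    v <- pop[, row$feature]
    switch(row$kind,
      continuous  = v,
      binary      = round(v),
      categorical = row$categories[[1]][as.integer(round(v))])
  })
  names(cols) <- features_tbl$feature
  tibble::as_tibble(cols)
}

# Decode an encoded population matrix over the unioned search space -- the
# representation risk models consume.
decode_population <- function(pop, union) {
  decode_matrix(pop, union$features)
}

# Render one encoded gene value for reports (binary -> label, categorical ->
# label, continuous rounded to `digits`).
render_gene <- function(row, value, digits = 3) {
  switch(row$kind,
    continuous  = formatC(value, format = "f", digits = digits, drop0trailing = TRUE),
    binary      = row$labels[[1]][as.integer(round(value)) + 1L],
    categorical = row$categories[[1]][as.integer(round(value))])
}
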