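#' Fit the tabular preprocessing transform for one disease table
#'
#' Learns, from a training table, the state needed to map raw rows into the
#' numeric design matrix the candidate models consume: per-column medians for
#' imputing missing numeric values, and ordered category-to-indicator maps for
#' one-hot expanding categorical columns. Identifier columns are dropped.
#'
#' @param table Raw tibble/data frame (rows = subjects).
#' @param schema Feature-registry rows covering the table's feature columns
#'   (their `kind` decides numeric vs one-hot treatment).
#' @param outcome Name of the binary outcome column.
#' @param drop Character vector of identifier columns to discard (default "id").
#' @return A `risk_preprocessor` object; apply it with [apply_preprocessor()].
#' @export
fit_preprocessor <- function(table, schema, outcome, drop = "id") {
  if (!outcome %in% names(table)) {
    stop("outcome column '", outcome, "' not found in table", call. = FALSE)
  }
  y <- table[[outcome]]
  if (!all(stats::na.omit(unique(y)) %in% c(0, 1))) {
    stop("outcome column '", outcome, "' must be binary 0/1", call. = FALSE)
  }
  feature_cols <- setdiff(names(table), c(outcome, drop))
  schema <- schema[match(feature_cols, schema$feature), , drop = FALSE]
  if (anyNA(schema$feature)) {
    stop("schema does not cover column(s): ",
         paste(setdiff(feature_cols, schema$feature), collapse = ", "),
         call. = FALSE)
  }
  medians <- list()
  levels_map <- list()
  for (i in seq_along(feature_cols)) {
    f <- feature_cols[i]
    if (schema$kind[i] == "categorical") {
      levels_map[[f]] <- schema$categories[[which(schema$feature == f)]]
    } else {
      medians[[f]] <- stats::median(table[[f]], na.rm = TRUE)
    }
  }
  structure(list(feature_cols = feature_cols, schema = schema,
                 outcome = outcome, drop = drop,
                 medians = medians, levels = levels_map),
            class = "risk_preprocessor")
}

#' Apply a fitted preprocessor to a table of raw rows
#'
#' Numeric missing values are replaced with the training medians; categorical
#' columns are one-hot expanded using the training category maps (a category
#' unseen at fit time maps to an all-zero indicator block, with a message).
#'
#' @param prep A [fit_preprocessor()] result.
#' @param table Raw tibble with the same feature columns (outcome optional).
#' @return Tibble of numeric columns (the design matrix as a tibble).
#' @export
apply_preprocessor <- function(prep, table) {
  out <- list()
  for (f in prep$feature_cols) {
    if (!f %in% names(table)) {
      stop("column '", f, "' missing from table", call. = FALSE)
    }
    if (f %in% names(prep$levels)) {
      lv <- prep$levels[[f]]
      v <- as.character(table[[f]])
      unseen <- setdiff(stats::na.omit(unique(v)), lv)
      if (length(unseen) > 0L) {
        message("unseen categor", if (length(unseen) > 1) "ies" else "y",
                " in '", f, "' mapped to all-zero block: ",
                paste(unseen, collapse = ", "))
      }
      for (l in lv) {
        out[[paste0(f, "__", gsub("[^A-Za-z0-9]+", "_", l))]] <-
          as.numeric(!is.na(v) & v == l)
      }
    } else {
      v <- as.numeric(table[[f]])
      v[is.na(v)] <- prep$medians[[f]]
      out[[f]] <- v
    }
  }
  tibble::as_tibble(out)
}

#' Seeded train/test row split
#'
#' @param table Tibble of rows.
#' @param ratio Training fraction in (0, 1); `round(ratio * n)` rows train.
#' @param seed Integer seed making the shuffle reproducible.
#' @return List with elements `train` and `test` (disjoint row subsets).
#' @export
#' @examples
#' split_train_test(tibble::tibble(x = 1:10), ratio = 0.8, seed = 1)
split_train_test <- function(table, ratio = 0.80, seed = 1L) {
  if (!(ratio > 0 && ratio < 1)) stop("ratio must lie in (0, 1)", call. = FALSE)
  n <- nrow(table)
  if (n < 2L) stop("need at least 2 rows to split", call. = FALSE)
  set.seed(seed)
  idx <- sample.int(n)
  n_train <- round(ratio * n)
  list(train = table[sort(idx[seq_len(n_train)]), , drop = FALSE],
       test  = table[sort(idx[-seq_len(n_train)]), , drop = FALSE])
}

#' Classification metric report
#'
#' Error metrics (MAE, MSE, RMSE, R squared) and accuracy are computed on the
#' hard 0/1 predictions, so for binary residuals MAE = MSE = 1 - accuracy and
#' RMSE = sqrt(MSE) hold identically. ROC AUC uses the continuous scores.
#'
#' @param truth Binary 0/1 outcome vector.
#' @param scores Predicted probabilities.
#' @param hard_predictions Binary 0/1 predictions (default: `scores >= 0.5`).
#' @param label Model label for the report row.
#' @return One-row tibble: `model, mae, mse, rmse, r2, roc_auc, accuracy`.
#'   `roc_auc` is `NA` when `truth` contains a single class (undefined).
#' @export
score_metrics <- function(truth, scores,
                          hard_predictions = as.numeric(scores >= 0.5),
                          label = "model") {
  stopifnot(length(truth) == length(scores),
            length(truth) == length(hard_predictions))
  err <- hard_predictions - truth
  mse <- mean(err^2)
  r2 <- 1 - sum(err^2) / sum((truth - mean(truth))^2)
  auc <- if (length(unique(truth)) < 2L) {
    NA_real_
  } else {
    as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
  }
  tibble::tibble(model = label,
                 mae = mean(abs(err)), mse = mse, rmse = sqrt(mse), r2 = r2,
                 roc_auc = auc, accuracy = mean(hard_predictions == truth))
}

#' Candidate model builders
#'
#' Each builder is a list with a `label`, a `fit(x, y)` function taking a
#' numeric design matrix and 0/1 outcome, and a `predict(fit, x)` function
#' returning probabilities — the pluggable contract consumed by
#' [train_and_select()].
#'
#' @param nrounds,max_depth,eta Boosting parameters (xgboost).
#' @param num_trees,seed Forest size and RNG seed (ranger).
#' @return A candidate-builder list.
#' @name candidates
NULL

#' @rdname candidates
#' @export
candidate_logistic <- function() {
  list(
    label = "logistic_regression",
    fit = function(x, y) {
      suppressWarnings(stats::glm.fit(cbind(`(Intercept)` = 1, x), y,
                                      family = stats::binomial()))
    },
    predict = function(fit, x) {
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0  # aliased (collinear one-hot) columns drop out
      as.numeric(stats::plogis(cbind(1, x) %*% beta))
    }
  )
}

#' @rdname candidates
#' @export
candidate_xgboost <- function(nrounds = 60L, max_depth = 4L, eta = 0.3) {
  list(
    label = "xgboost",
    fit = function(x, y) {
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = max_depth,
                      eta = eta, nthread = 1),
        data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
        nrounds = nrounds, verbose = 0)
    },
    predict = function(fit, x) {
      as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(x, nthread = 1)))
    }
  )
}

#' @rdname candidates
#' @export
candidate_random_forest <- function(num_trees = 300L, seed = 1L) {
  list(
    label = "random_forest",
    fit = function(x, y) {
      ranger::ranger(x = as.data.frame(x), y = factor(y, levels = c(0, 1)),
                     probability = TRUE, num.trees = num_trees, seed = seed,
                     num.threads = 1)
    },
    predict = function(fit, x) {
      as.numeric(stats::predict(fit, as.data.frame(x),
                                num.threads = 1)$predictions[, "1"])
    }
  )
}

#' Wrap an arbitrary probability function as a risk model
#'
#' The optimiser treats every disease model as a black box satisfying this
#' adapter contract: a feature order and a deterministic function mapping raw
#' feature rows to probabilities in \[0, 1\].
#'
#' @param disease Disease identifier.
#' @param feature_order Character vector: the model's input columns, in order.
#' @param predict_function Function: raw tibble with those columns ->
#'   probability vector.
#' @param label Model label (default "custom").
#' @return A `risk_model` object.
#' @export
make_risk_model <- function(disease, feature_order, predict_function,
                            label = "custom") {
  structure(list(disease = disease, feature_order = feature_order,
                 predict_function = predict_function, label = label),
            class = "risk_model")
}

#' Predicted disease probability for raw feature rows
#'
#' @param model A `risk_model`.
#' @param newdata Tibble containing the model's feature columns (raw values;
#'   categorical columns as labels).
#' @return Numeric vector of probabilities in \[0, 1\]; errors if the
#'   underlying model emits anything outside that range.
#' @export
predict_probability <- function(model, newdata) {
  stopifnot(inherits(model, "risk_model"))
  p <- model$predict_function(newdata[, model$feature_order, drop = FALSE])
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("model '", model$label, "' (", model$disease,
         ") returned probabilities outside [0, 1]", call. = FALSE)
  }
  as.numeric(p)
}

#' @export
print.risk_model <- function(x, ...) {
  cat("<risk_model> ", x$disease, " [", x$label, "], features: ",
      paste(x$feature_order, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Train every candidate, score on held-out rows, keep the ROC-AUC winner
#'
#' All candidates are fitted on the (preprocessed) training rows and scored on
#' the test rows; the candidate with the highest ROC AUC wins, ties broken by
#' higher accuracy and then candidate order. The winner is wrapped as a
#' [make_risk_model()] adapter that applies the fitted preprocessing to any
#' raw input row.
#'
#' @param train,test Raw tibbles including the outcome column.
#' @param candidates List of candidate builders (see [candidates]).
#' @param disease Disease identifier.
#' @param schema Feature-registry rows covering the feature columns.
#' @param outcome Outcome column name.
#' @param threshold Score threshold for hard 0/1 predictions (default 0.5).
#' @return List: `model` (a `risk_model`), `metrics` (tibble, one row per
#'   candidate, winner first marked by `selected`).
#' @export
train_and_select <- function(train, test, candidates, disease, schema, outcome,
                             threshold = 0.5) {
  if (length(candidates) < 1L) stop("need at least one candidate", call. = FALSE)
  prep <- fit_preprocessor(train, schema, outcome)
  x_train <- as.matrix(apply_preprocessor(prep, train))
  x_test <- as.matrix(apply_preprocessor(prep, test))
  y_train <- train[[outcome]]
  y_test <- test[[outcome]]

  fits <- list(); reports <- list(); failures <- character()
  for (cand in candidates) {
    res <- tryCatch({
      fit <- cand$fit(x_train, y_train)
      scores <- cand$predict(fit, x_test)
      list(fit = fit,
           metrics = score_metrics(y_test, scores,
                                   as.numeric(scores >= threshold),
                                   label = cand$label))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, paste0(cand$label, ": ", conditionMessage(res)))
    } else {
      fits[[cand$label]] <- list(fit = res$fit, builder = cand)
      reports[[cand$label]] <- res$metrics
    }
  }
  if (length(fits) == 0L) {
    stop("all candidates failed to train:\n  ",
         paste(failures, collapse = "\n  "), call. = FALSE)
  }
  metrics <- dplyr::bind_rows(reports)
  ord <- order(-metrics$roc_auc, -metrics$accuracy, seq_len(nrow(metrics)))
  winner_label <- metrics$model[ord[1]]
  metrics$selected <- metrics$model == winner_label
  winner <- fits[[winner_label]]

  predict_fn <- function(newdata) {
    winner$builder$predict(winner$fit,
                           as.matrix(apply_preprocessor(prep, newdata)))
  }
  model <- make_risk_model(disease, prep$feature_cols, predict_fn,
                           label = winner_label)
  model$preprocessor <- prep
  list(model = model, metrics = metrics)
}
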