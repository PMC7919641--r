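LEARNER_NAMES <- c("random_forest", "logit_boost", "gradient_boosted_trees")

#' Default hyperparameter grids
#'
#' Small documented defaults (the source analysis used framework defaults it
#' never lists): gradient boosting searches trees x depth x learning rate,
#' the forest searches `mtry` in sqrt(p) and p/3, LogitBoost searches its
#' iteration count.
#'
#' @param learner_name one of `random_forest`, `logit_boost`,
#'   `gradient_boosted_trees`.
#' @param p number of predictors.
#' @return data.frame, one row per hyperparameter configuration.
#' @export
default_grid <- function(learner_name, p = 14L) {
  switch(learner_name,
    gradient_boosted_trees = expand.grid(nrounds = c(100L, 300L),
                                         max_depth = c(2L, 4L, 6L),
                                         eta = c(0.1, 0.3)),
    random_forest = data.frame(mtry = unique(c(max(1L, floor(sqrt(p))),
                                               max(1L, floor(p / 3))))),
    logit_boost = data.frame(niter = c(20L, 50L)),
    stop_invalid("unknown learner: ", learner_name))
}

#' Fit a probabilistic binary classifier
#'
#' All learners are in-package tree ensembles sharing one second-order
#' exact-greedy tree grower: `gradient_boosted_trees` is logistic-loss
#' Newton boosting with L2 leaf regularization, `random_forest` averages
#' bootstrap Gini trees with per-node feature subsampling, and
#' `logit_boost` is classic additive logistic boosting with depth-1 stumps.
#'
#' @param learner_name one of `random_forest`, `logit_boost`,
#'   `gradient_boosted_trees`.
#' @param x numeric predictor matrix.
#' @param y logical (or 0/1) labels; `TRUE` is the positive (PGx) class.
#' @param params named list / one-row data.frame of hyperparameters (see
#'   [default_grid()]).
#' @param seed integer seed (consumed by the forest's bootstrap only; the
#'   boosted learners are deterministic).
#' @return object of class `pgx_model`.
#' @export
fit_learner <- function(learner_name, x, y, params = NULL, seed = 1L) {
  learner_name <- match.arg(learner_name, LEARNER_NAMES)
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) stop_invalid("labels contain a single class")
  params <- as.list(params %||% default_grid(learner_name, ncol(x))[1, ,
                                             drop = FALSE])
  fit <- switch(learner_name,
    gradient_boosted_trees = cpp_gbt_fit(
      x, y, nrounds = as.integer(params$nrounds %||% 100L),
      eta = params$eta %||% 0.3,
      max_depth = as.integer(params$max_depth %||% 4L),
      lambda = params$lambda %||% 1.0,
      min_child_weight = params$min_child_weight %||% 1.0),
    random_forest = cpp_rf_fit(
      x, y, ntree = as.integer(params$ntree %||% 300L),
      mtry = as.integer(params$mtry %||% max(1L, floor(sqrt(ncol(x))))),
      max_depth = as.integer(params$max_depth %||% 20L),
      min_node = as.integer(params$min_node %||% 5L),
      seed = as.numeric(seed)),
    logit_boost = cpp_logitboost_fit(
      x, y, niter = as.integer(params$niter %||% 50L)))
  structure(list(learner_name = learner_name, fit = fit, params = params,
                 feature_names = colnames(x)),
            class = "pgx_model")
}

#' Predict class-1 probabilities
#'
#' @param model a `pgx_model` from [fit_learner()].
#' @param x predictor matrix with the training columns.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict_prob <- function(model, x) {
  stopifnot(inherits(model, "pgx_model"))
  x <- as.matrix(x)
  if (!is.null(model$feature_names) && !is.null(colnames(x)))
    x <- x[, model$feature_names, drop = FALSE]
  switch(model$learner_name,
    gradient_boosted_trees = cpp_gbt_predict(model$fit, x),
    random_forest = cpp_forest_predict(model$fit, x),
    logit_boost = cpp_logitboost_predict(model$fit, x))
}

#' Gain-based variable importance
#'
#' Total split gain accumulated per predictor across all trees, rescaled so
#' the top variable scores exactly 100, in descending order.
#'
#' @param model a fitted `pgx_model`.
#' @return data.frame `variable`, `importance` (max exactly 100).
#' @export
variable_importance <- function(model) {
  stopifnot(inherits(model, "pgx_model"))
  imp <- model$fit$importance
  names(imp) <- model$feature_names %||% paste0("x", seq_along(imp))
  if (max(imp) > 0) imp <- imp / max(imp) * 100
  imp <- sort(imp, decreasing = TRUE)
  data.frame(variable = names(imp), importance = as.numeric(imp),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Probabilities on `newx` for every row of `grid` in one pass. Boosted fits
# are sequential, so the first k trees of a long fit ARE the k-round fit:
# one fit per (depth, eta) group serves the whole nrounds/niter axis,
# producing results identical to fitting each row separately.
predict_grid_probs <- function(learner_name, x, y, grid, newx, seed) {
  newx <- as.matrix(newx)
  probs <- matrix(NA_real_, nrow(newx), nrow(grid))
  staged_axis <- switch(learner_name,
                        gradient_boosted_trees = "nrounds",
                        logit_boost = "niter", NULL)
  if (!is.null(staged_axis) && staged_axis %in% names(grid)) {
    other <- setdiff(names(grid), staged_axis)
    key <- if (length(other))
      do.call(paste, c(grid[other], list(sep = "\r")))
    else rep("", nrow(grid))
    for (grp in split(seq_len(nrow(grid)), key)) {
      grp <- grp[order(grid[[staged_axis]][grp])]
      fit <- fit_learner(learner_name, x, y,
                         as.list(grid[grp[length(grp)], , drop = FALSE]),
                         seed)
      checkpoints <- as.integer(grid[[staged_axis]][grp])
      probs[, grp] <- if (learner_name == "gradient_boosted_trees")
        cpp_gbt_predict_multi(fit$fit, newx, checkpoints)
      else cpp_logitboost_predict_multi(fit$fit, newx, checkpoints)
    }
  } else {
    for (gi in seq_len(nrow(grid))) {
      fit <- fit_learner(learner_name, x, y,
                         as.list(grid[gi, , drop = FALSE]), seed)
      probs[, gi] <- predict_prob(fit, newx)
    }
  }
  probs
}

#' @export
print.pgx_model <- function(x, ...) {
  cat("pgxpredict model:", x$learner_name, "\n")
  cat("  params:", paste(names(x$params), unlist(x$params), sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}
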