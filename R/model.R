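#' Stratified train/test partition
#'
#' Samples `round(class_count * train_fraction)` members of each class into
#' the training set (matching the conventional stratified-partition
#' behavior), the rest into the test set.
#'
#' @param labels logical (or two-level) class labels; both classes must be
#'   present.
#' @param train_fraction fraction of each class assigned to training;
#'   default 0.70.
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
stratified_partition <- function(labels, train_fraction = 0.70, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_invalid("train_fraction must lie in (0, 1)")
  lev <- unique(labels)
  if (length(lev) < 2L || any(table(labels) == 0L))
    stop_invalid("both classes must be present")
  with_seed(seed, {
    train <- integer(0)
    for (lv in lev) {
      idx <- which(labels == lv)
      n_tr <- round(length(idx) * train_fraction)
      train <- c(train, idx[sample.int(length(idx), n_tr)])
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train))
  })
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin over folds, so every sample is in exactly one assessment fold
# and fold class proportions match the data.
stratified_folds <- function(labels, folds, seed) {
  with_seed(seed, {
    fold_of <- integer(length(labels))
    for (lv in unique(labels)) {
      idx <- which(labels == lv)
      fold_of[idx[sample.int(length(idx))]] <-
        rep_len(seq_len(folds), length(idx))
    }
    fold_of
  })
}

#' Six-number summaries of resample metrics
#'
#' Min, first quartile, median, mean, third quartile, max per metric column,
#' quartiles by the linear-interpolation convention (`quantile` type 7).
#'
#' @param resample_metrics data.frame of per-resample metrics (e.g. columns
#'   `roc_auc`, `sensitivity`, `specificity`).
#' @return data.frame, one row per metric with columns `metric`, `min`,
#'   `q1`, `median`, `mean`, `q3`, `max`.
#' @export
summarize_resamples <- function(resample_metrics) {
  cols <- names(resample_metrics)
  rows <- lapply(cols, function(cc) {
    v <- resample_metrics[[cc]]
    if (length(v) == 0L) stop_invalid("empty metric vector: ", cc)
    q <- quantile(v, c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
    data.frame(metric = cc, min = q[1], q1 = q[2], median = q[3],
               mean = mean(v), q3 = q[4], max = q[5],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Repeated stratified cross-validation with in-resample SMOTE
#'
#' Runs `folds`-fold cross-validation repeated `repeats` times (50 resamples
#' at the 5 x 10 default). Within each resample, SMOTE balances the analysis
#' folds only — the assessment fold never contributes to synthesis — and
#' every hyperparameter configuration in the grid is fitted on the same
#' balanced set. The configuration maximizing the mean selection metric over
#' all resamples is chosen; its per-resample metrics are kept, and a final
#' model is refitted on the SMOTE-balanced full training data.
#'
#' @param learner_name one of `random_forest`, `logit_boost`,
#'   `gradient_boosted_trees`.
#' @param x predictor matrix.
#' @param y logical labels (`TRUE` = annotated PGx, the positive class).
#' @param folds,repeats cross-validation geometry (defaults 5 and 10).
#' @param selection_metric `"sensitivity"` (default, the source analysis'
#'   choice) or `"roc_auc"`.
#' @param smote_config a [smote_config()]; its seed field is ignored
#'   (per-resample seeds derive from `seed`).
#' @param grid hyperparameter data.frame; defaults to
#'   [default_grid()].
#' @param threshold classification threshold for sens/spec (default 0.5).
#' @param seed master seed, expanded deterministically into fold, SMOTE and
#'   learner seeds.
#' @param keep_provenance keep per-resample SMOTE provenance (analysis
#'   indices, synthesis parents/neighbors) for leakage auditing.
#' @return object of class `pgx_cv` with elements `learner_name`,
#'   `resample_metrics` (folds x repeats rows of `roc_auc`, `sensitivity`,
#'   `specificity`), `chosen_hyperparameters`, `summary`, `grid_means`,
#'   `model` (final fitted `pgx_model`) and optionally `provenance`.
#' @export
repeated_cv_train <- function(learner_name, x, y, folds = 5L, repeats = 10L,
                              selection_metric = c("sensitivity", "roc_auc"),
                              smote_config = pgxpredict::smote_config(),
                              grid = NULL, threshold = 0.5, seed = 1L,
                              keep_provenance = FALSE) {
  learner_name <- match.arg(learner_name, LEARNER_NAMES)
  selection_metric <- match.arg(selection_metric)
  x <- as.matrix(x); y <- as.logical(y)
  if (folds < 2L) stop_invalid("folds must be >= 2")
  if (min(table(y)) < folds)
    stop_invalid("cannot stratify: the rarer class has fewer members (",
                 min(table(y)), ") than folds (", folds, ")")
  grid <- grid %||% default_grid(learner_name, ncol(x))
  n_res <- folds * repeats
  seeds <- derive_seeds(seed, repeats + n_res + n_res + 2L)
  fold_seeds <- seeds[seq_len(repeats)]
  smote_seeds <- seeds[repeats + seq_len(n_res)]
  fit_seeds <- seeds[repeats + n_res + seq_len(n_res)]

  metrics <- vector("list", nrow(grid))
  for (gi in seq_len(nrow(grid)))
    metrics[[gi]] <- data.frame(resample = character(n_res),
                                roc_auc = numeric(n_res),
                                sensitivity = numeric(n_res),
                                specificity = numeric(n_res),
                                stringsAsFactors = FALSE)
  provenance <- if (keep_provenance) vector("list", n_res) else NULL

  r <- 0L
  for (rep_i in seq_len(repeats)) {
    fold_of <- stratified_folds(y, folds, fold_seeds[rep_i])
    for (k in seq_len(folds)) {
      r <- r + 1L
      assess <- which(fold_of == k)
      analysis <- which(fold_of != k)
      if (length(unique(y[assess])) < 2L)
        stop_invalid("assessment fold ", k, " of repeat ", rep_i,
                     " contains a single class; use fewer folds")
      sc <- smote_config
      sc$seed <- smote_seeds[r]
      bal <- smote_sample(x[analysis, , drop = FALSE], y[analysis], sc)
      if (keep_provenance) {
        prov <- bal$provenance
        # map provenance rows back to global indices
        prov$parent <- analysis[prov$parent]
        prov$neighbor <- analysis[prov$neighbor]
        prov$minority <- analysis[prov$minority]
        prov$majority_kept <- analysis[prov$majority_kept]
        prov$analysis <- analysis
        prov$assess <- assess
        provenance[[r]] <- prov
      }
      probs <- predict_grid_probs(learner_name, bal$x, bal$labels, grid,
                                  x[assess, , drop = FALSE], fit_seeds[r])
      ya <- y[assess]
      for (gi in seq_len(nrow(grid))) {
        prob <- probs[, gi]
        pred <- prob >= threshold
        metrics[[gi]][r, ] <- list(sprintf("Fold%d.Rep%d", k, rep_i),
                                   auc(prob, ya),
                                   sum(pred & ya) / sum(ya),
                                   sum(!pred & !ya) / sum(!ya))
      }
    }
  }
  sel_col <- if (selection_metric == "roc_auc") "roc_auc" else "sensitivity"
  grid_means <- cbind(grid,
                      mean_metric = vapply(metrics, function(m)
                        mean(m[[sel_col]]), numeric(1)))
  best <- which.max(grid_means$mean_metric)
  best_metrics <- metrics[[best]]

  # final fit: SMOTE-balance the full training data, refit best config
  sc <- smote_config
  sc$seed <- seeds[repeats + 2L * n_res + 1L]
  bal <- smote_sample(x, y, sc)
  final <- fit_learner(learner_name, bal$x, bal$labels,
                       params = grid[best, , drop = FALSE],
                       seed = seeds[repeats + 2L * n_res + 2L])

  structure(list(learner_name = learner_name,
                 resample_metrics = best_metrics,
                 chosen_hyperparameters = lapply(grid, `[`, best),
                 summary = summarize_resamples(
                   best_metrics[, c("roc_auc", "sensitivity", "specificity")]),
                 grid_means = grid_means,
                 threshold = threshold,
                 model = final,
                 provenance = provenance),
            class = "pgx_cv")
}

#' @export
print.pgx_cv <- function(x, ...) {
  cat("Repeated CV:", x$learner_name, "-",
      nrow(x$resample_metrics), "resamples\n")
  cat("  chosen:", paste(names(x$chosen_hyperparameters),
                         unlist(x$chosen_hyperparameters), sep = "=",
                         collapse = ", "), "\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Predict new (not yet annotated) PGx variants
#'
#' Returns the ids of variants whose predicted probability reaches the
#' threshold and that are *not* in the annotated set — the candidate novel
#' pharmacovariants.
#'
#' @param model fitted `pgx_model`.
#' @param x predictor matrix with variant ids as rownames.
#' @param annotated_id_set character vector of already-annotated ids.
#' @param threshold probability cutoff (default 0.5).
#' @return character vector of newly predicted variant ids.
#' @export
predict_new <- function(model, x, annotated_id_set = character(0),
                        threshold = 0.5) {
  prob <- predict_prob(model, x)
  ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  setdiff(ids[prob >= threshold], annotated_id_set)
}
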