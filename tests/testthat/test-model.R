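test_that("stratified partition keeps per-class proportions", {
  labels <- rep(c(TRUE, FALSE), c(20, 80))
  part <- stratified_partition(labels, seed = 3)  # default fraction 0.70
  expect_equal(sum(labels[part$train]), 14L)
  expect_lte(abs(length(part$train) - 70L), 1L)
  expect_identical(sort(c(part$train, part$test)), seq_along(labels))
  expect_length(intersect(part$train, part$test), 0L)
  expect_error(stratified_partition(rep(TRUE, 10)),
               class = "pgx_invalid_argument")
  expect_error(stratified_partition(labels, train_fraction = 1),
               class = "pgx_invalid_argument")
})

test_that("fold assignment is a stratified partition per repeat", {
  y <- rep(c(TRUE, FALSE), c(40, 160))
  for (seed in 1:3) {
    fold_of <- pgxpredict:::stratified_folds(y, 5L, seed)
    expect_setequal(unique(fold_of), 1:5)
    # every sample in exactly one fold; class balance within +/- 1
    expect_length(fold_of, 200L)
    per_fold_pos <- tapply(y, fold_of, sum)
    expect_true(max(per_fold_pos) - min(per_fold_pos) <= 1)
  }
})

test_that("six-number summaries use the linear-interpolation convention", {
  s <- summarize_resamples(data.frame(m = rep(0.9, 7)))
  expect_equal(unlist(s[1, c("min", "q1", "median", "mean", "q3", "max")],
                      use.names = FALSE), rep(0.9, 6))
  s2 <- summarize_resamples(data.frame(m = c(0.1, 0.2, 0.3, 0.4)))
  expect_equal(s2$median, 0.25)
  expect_equal(s2$q1, 0.175)
  expect_equal(s2$mean, 0.25)
})

test_that("repeated CV yields folds x repeats resamples and perfect recall on separable data", {
  d <- separable_data(n = 400, seed = 6)
  cv <- repeated_cv_train("gradient_boosted_trees", d$x, d$y,
                          folds = 5, repeats = 10,
                          grid = data.frame(nrounds = 30L, max_depth = 2L,
                                            eta = 0.3),
                          smote_config = smote_config(perc_under = 100),
                          seed = 21)
  expect_equal(nrow(cv$resample_metrics), 50L)
  expect_equal(median(cv$resample_metrics$sensitivity), 1.0)
  expect_true(all(cv$resample_metrics$roc_auc >= 0 &
                  cv$resample_metrics$roc_auc <= 1))
  expect_s3_class(cv$model, "pgx_model")
  expect_error(repeated_cv_train("gradient_boosted_trees", d$x, d$y,
                                 folds = 1),
               class = "pgx_invalid_argument")
})

test_that("confusion matrices behave at the edges", {
  y <- rep(c(TRUE, FALSE), c(5, 15))
  perfect <- evaluate_test(as.numeric(y), test_labels = y)
  expect_equal(perfect$fp, 0L)
  expect_equal(perfect$fn, 0L)
  all_neutral <- evaluate_test(rep(0.01, 20), test_labels = y)
  expect_equal(all_neutral$tp, 0L)
  expect_equal(all_neutral$tn, 15L)
  expect_error(evaluate_test(rep(0.5, 3), test_labels = y),
               class = "pgx_invalid_argument")
  expect_error(evaluate_test(as.numeric(y), test_labels = y, threshold = 0),
               class = "pgx_invalid_argument")
  # abstentions: dropped by default, counted as neutral on request
  pr <- c(NA, as.numeric(y[-1]))
  cm_drop <- evaluate_test(pr, test_labels = y)
  expect_equal(cm_drop$tp + cm_drop$fn, 4L)
  cm_keep <- evaluate_test(pr, test_labels = y, count_abstentions = TRUE)
  expect_equal(cm_keep$tp + cm_keep$fn, 5L)
  expect_equal(cm_keep$fn, 1L)
})

test_that("sens/spec/accuracy recompute correctly from published-style counts", {
  cm <- confusion_matrix(tp = 140, fp = 686, tn = 10716, fn = 63)
  m <- compute_metrics(cm, "gbt")
  expect_equal(m$sensitivity, 140 / 203, tolerance = 1e-12)
  expect_equal(m$specificity, 10716 / 11402, tolerance = 1e-12)
  expect_equal(m$accuracy, 10856 / 11605, tolerance = 1e-12)
  expect_equal(round(c(m$sensitivity, m$specificity, m$accuracy), 3),
               c(0.690, 0.940, 0.935))
  expect_error(compute_metrics(confusion_matrix(0, 0, 5, 0)),
               class = "pgx_invalid_argument")
})

test_that("AUC equals exhaustive pair counting, including ties", {
  expect_equal(auc(c(0.9, 0.8, 0.4), c(TRUE, FALSE, TRUE)), 0.5)
  expect_equal(auc(c(1, 1, 0, 0), c(TRUE, TRUE, FALSE, FALSE)), 1.0)
  set.seed(17)
  for (i in 1:5) {
    n <- sample(20:200, 1)
    scores <- round(runif(n), 1)   # coarse grid forces ties
    labels <- runif(n) < 0.4
    if (length(unique(labels)) < 2) next
    expect_equal(auc(scores, labels), auc_oracle(scores, labels))
  }
  expect_error(auc(1:3, rep(TRUE, 3)), class = "pgx_undefined_metric")
})

test_that("comparator metrics: perfect score, constant score, missingness", {
  labels <- rep(c(TRUE, FALSE), c(10, 30))
  scores <- data.frame(oracle = as.numeric(labels),
                       coin = rep(0.5, 40),
                       sparse = c(NA, as.numeric(labels[-1])))
  res <- comparator_metrics(scores, labels,
                            thresholds = c(oracle = 0.5, coin = 0.5,
                                           sparse = 0.5))
  oracle <- res[res$method_name == "oracle", ]
  expect_equal(oracle$sensitivity, 1)
  expect_equal(oracle$specificity, 1)
  expect_equal(oracle$accuracy, 1)
  expect_equal(oracle$auc, 1)
  expect_equal(res$auc[res$method_name == "coin"], 0.5)  # all ties
  expect_equal(res$n_used[res$method_name == "sparse"], 39L)

  # a "lower = damaging" score flips both threshold and AUC direction
  res2 <- comparator_metrics(data.frame(sift = 1 - as.numeric(labels)),
                             labels, thresholds = c(sift = 0.05),
                             directions = c(sift = "lower"))
  expect_equal(res2$auc, 1)
  expect_equal(res2$sensitivity, 1)
})

test_that("predict_new filters by threshold and annotation", {
  d <- separable_data(n = 200, seed = 8)
  rownames(d$x) <- paste0("v", seq_len(nrow(d$x)))
  fit <- fit_learner("gradient_boosted_trees", d$x, d$y,
                     list(nrounds = 30, max_depth = 2, eta = 0.3))
  prob <- predict_prob(fit, d$x)
  annotated <- rownames(d$x)[d$y][1:50]
  new_ids <- predict_new(fit, d$x, annotated, threshold = 0.5)
  expect_length(intersect(new_ids, annotated), 0L)
  expect_setequal(new_ids,
                  setdiff(rownames(d$x)[prob >= 0.5], annotated))
  if (all(prob < 1))
    expect_length(predict_new(fit, d$x, character(0), threshold = 1.0), 0L)
})

test_that("MAF-only class signal puts MAF first in importance across seeds", {
  hits <- 0L
  for (seed in 1:10) {
    cfg <- sim_config(n_genes = 150, n_variants = 3000, seed = seed)
    # flatten every non-MAF signal
    for (fld in c("ep_ref_beta", "ep_alt_beta", "evo_rate_beta",
                  "evo_time_beta", "flag_rates"))
      cfg[[fld]] <- setNames(rep(cfg[[fld]]["neutral"], 3),
                             names(cfg[[fld]]))
    cfg$cap_prob[] <- 0.05
    genes <- generate_genes(150, 0.05, seed = seed)
    vt <- generate_variant_table(genes, config = cfg)
    mm <- model_matrix_from_variants(vt$variants)
    fit <- fit_learner("gradient_boosted_trees", mm$matrix, mm$label,
                       list(nrounds = 50, max_depth = 3, eta = 0.3))
    if (variable_importance(fit)$variable[1] == "maf") hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
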