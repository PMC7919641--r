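make_af_table <- function(af_by_panel) {
  panel <- population_panel()
  n <- nrow(af_by_panel)
  df <- data.frame(variant_id = paste0("v", seq_len(n)))
  for (lab in panel$label)
    df[[lab]] <- if (lab %in% colnames(af_by_panel)) af_by_panel[, lab]
                 else rep(0, n)
  df
}

test_that("venn partition classifies group presence correctly", {
  af <- make_af_table(cbind(YRI = c(0.3, 0, 0.2), GBR = c(0, 0.5, 0.1)))
  vn <- venn_partition(af)
  expect_equal(vn$non_eur_only, 1L)
  expect_equal(vn$eur_only, 1L)
  expect_equal(vn$shared, 1L)
  expect_equal(vn$total, 3L)
  expect_equal(vn$fraction_carried_by_non_europeans, 2 / 3)

  # all variants common everywhere
  all_common <- make_af_table(matrix(0.5, 4, 26,
    dimnames = list(NULL, population_panel()$label)))
  vn2 <- venn_partition(all_common)
  expect_equal(vn2$shared, vn2$total)
  expect_equal(vn2$fraction_carried_by_non_europeans, 1.0)

  # monomorphic variants are excluded from the partition
  af3 <- make_af_table(cbind(YRI = c(0.2, 0)))
  expect_equal(venn_partition(af3)$total, 1L)

  expect_error(venn_partition(af[, -2]), class = "pgx_invalid_argument")
})

test_that("venn partition is invariant to population column order", {
  w <- tiny_world(seed = 13, n_variants = 600)
  v1 <- venn_partition(w$vt$pop_af)
  shuffled <- w$vt$pop_af[, c(1, sample(2:27))]
  v2 <- venn_partition(shuffled)
  expect_identical(unclass(v1), unclass(v2))
})

test_that("zero divergence makes every polymorphic variant shared", {
  cfg <- sim_config(n_genes = 100, pgx_fraction = 0.2, n_variants = 400,
                    divergence_fst = 0, african_shift = 0, seed = 19)
  genes <- generate_genes(100, 0.2, seed = 19)
  vt <- generate_variant_table(genes, config = cfg)
  vn <- venn_partition(vt$pop_af)
  expect_equal(vn$shared, vn$total)
})

test_that("category counts partition the pharmacogenes and refine consistently", {
  w <- tiny_world(seed = 23, n_variants = 800)
  predicted <- sample(w$vt$variants$variant_id, 25)
  cc <- counts_by_category(w$genes, predicted, w$vt$variants)
  expect_equal(sum(cc$summary$n_genes), sum(w$genes$is_pharmacogene))
  expect_equal(nrow(cc$per_gene), sum(w$genes$is_pharmacogene))
  # a gene with no predicted variants contributes 0
  expect_true(any(cc$per_gene$n_predicted == 0))
  # total predicted-in-pharmacogene variants conserved
  expect_equal(sum(cc$per_gene$n_predicted),
               sum(w$vt$variants$variant_id %in% predicted))

  # refinement: one coarse bin vs unit bins conserves gene sets and totals
  rng <- range(w$genes$cpic_drug_count[w$genes$is_pharmacogene])
  coarse <- counts_by_category(w$genes, predicted, w$vt$variants,
                               bins = list(all = seq(rng[1], rng[2])))
  expect_equal(sum(coarse$summary$total_predicted),
               sum(cc$summary$total_predicted))
  expect_equal(coarse$summary$n_genes, sum(cc$summary$n_genes))

  expect_error(counts_by_category(w$genes, predicted, w$vt$variants,
                                  bins = list(a = 0:2, b = 2:5)),
               class = "pgx_invalid_argument")
})

test_that("AF-by-class table has 26 x classes rows with correct medians", {
  w <- tiny_world(seed = 29, n_variants = 900)
  cls <- w$vt$variants$class
  out <- af_by_class_population(w$vt$pop_af, cls)
  expect_equal(nrow(out), 26L * 3L)
  # single-variant class: median equals its AF in each panel
  cls2 <- cls
  cls2[1] <- "solo"
  cls2[-1][cls2[-1] == "solo"] <- "neutral"
  out2 <- af_by_class_population(w$vt$pop_af, cls2)
  solo <- out2[out2$class == "solo", ]
  expect_equal(solo$median,
               as.numeric(w$vt$pop_af[1, solo$population]))
  # default generator: functional classes commoner than neutral everywhere
  med <- reshape(out[, c("population", "class", "median")],
                 direction = "wide", idvar = "population",
                 timevar = "class")
  expect_true(all(med$median.annotated > med$median.neutral))
  expect_true(all(med$median.predicted > med$median.neutral))
})

test_that("pipeline smoke run writes all artifacts", {
  cfg <- default_pipeline_config(seed = 5)
  cfg$simulate$n_variants <- 1200L
  cfg$simulate$n_genes <- 400L
  out <- tempfile("pgxsmoke")
  res <- run_pipeline(cfg, out)
  expected <- c("genes.tsv", "variants.tsv", "pop_af.tsv", "enrichment.tsv",
                "model_matrix.tsv", "resamples.tsv", "cv_summary.tsv",
                "importance.tsv", "confusion.tsv", "test_metrics.tsv",
                "predictions.tsv", "predicted_ids.txt", "venn.tsv",
                "category_counts.tsv", "af_by_class.tsv", "manifest.json")
  expect_true(all(file.exists(file.path(out, expected))))
  expect_equal(nrow(res$train$cv$resample_metrics),
               cfg$train$folds * cfg$train$repeats)
})

test_that("pipeline failures name the failing stage", {
  cfg <- default_pipeline_config(seed = 5)
  cfg$train$learner <- "not_a_learner"
  expect_error(run_pipeline(cfg, tempfile()), "stage 'train'")
  expect_error(run_pipeline("/nonexistent/config.json", tempfile()),
               "config")
})
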