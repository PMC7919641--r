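#' Default end-to-end pipeline configuration
#'
#' A desk-scale synthetic run: 2000-gene universe (5% pharmacogenes), 4000
#' variants, enrichment over three signature statistics, gradient-boosted
#' training with a compact grid, and all downstream reports. Sizes are kept
#' small so a full run finishes in well under a minute; scale fields up for
#' the criterion-scale world.
#'
#' @param seed master seed for the whole run.
#' @return nested list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(n_genes = 2000L, pgx_fraction = 0.05,
                    n_variants = 4000L, enrichment_factor = 3),
    enrich = list(n_permutations = 1000L),
    train = list(learner = "gradient_boosted_trees",
                 folds = 5L, repeats = 2L,
                 selection_metric = "sensitivity",
                 grid = data.frame(nrounds = 100L, max_depth = c(2L, 4L),
                                   eta = 0.3),
                 threshold = 0.5,
                 train_fraction = 0.70),
    report = list(presence_threshold = 0))
}

read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_pipeline_config(seed = cfg$seed %||% 1L)
  modifyList(base, cfg)
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full synthetic pipeline
#'
#' Executes simulate -> enrich -> features -> train -> evaluate -> predict
#' -> report under one master seed and writes every artifact (TSV tables, a
#' JSON manifest with seeds and input hashes) into `out_dir`. Two runs with
#' the same config produce byte-identical numeric outputs.
#'
#' @param config nested list, see [default_pipeline_config()], or a path to
#'   a JSON file with the same structure.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory results of each stage.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = tempfile("pgxrun")) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("pipeline stage 'config' failed: config file not found: ",
           config, call. = FALSE)
    config <- read_pipeline_config(config)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 6L)
  tsv <- function(x, name) {
    data.table::fwrite(data.table::as.data.table(x),
                       file.path(out_dir, name), sep = "\t")
  }

  sim <- pipeline_stage("simulate", {
    sc <- config$simulate
    genes <- generate_genes(sc$n_genes, sc$pgx_fraction, seed = seeds[1])
    cfg <- sim_config(n_genes = sc$n_genes, pgx_fraction = sc$pgx_fraction,
                      n_variants = sc$n_variants, seed = seeds[2])
    vt <- generate_variant_table(genes, config = cfg)
    sigs <- generate_adaptive_signatures(
      genes, enrichment_factor = sc$enrichment_factor %||% 1,
      seed = seeds[3])
    tsv(genes, "genes.tsv")
    tsv(vt$variants, "variants.tsv")
    tsv(vt$pop_af, "pop_af.tsv")
    for (nm in names(sigs))
      writeLines(sigs[[nm]], file.path(out_dir, paste0("signature_",
                                                       gsub("[^A-Za-z0-9]", "_", nm), ".txt")))
    list(genes = genes, vt = vt, sigs = sigs)
  })

  enr <- pipeline_stage("enrich", {
    res <- enrichment_test(nrow(sim$genes),
                           sim$genes$gene_id[sim$genes$is_pharmacogene],
                           sim$sigs,
                           n_permutations = config$enrich$n_permutations,
                           seed = seeds[4])
    tsv(res, "enrichment.tsv")
    res
  })

  feat <- pipeline_stage("features", {
    mm <- model_matrix_from_variants(sim$vt$variants)
    write_model_matrix(mm$matrix, file.path(out_dir, "model_matrix.tsv"))
    mm
  })

  tr <- pipeline_stage("train", {
    tc <- config$train
    part <- stratified_partition(feat$label, tc$train_fraction, seeds[5])
    grid <- tc$grid
    if (!is.null(grid) && !is.data.frame(grid)) grid <- as.data.frame(grid)
    cv <- repeated_cv_train(tc$learner, feat$matrix[part$train, ],
                            feat$label[part$train],
                            folds = tc$folds, repeats = tc$repeats,
                            selection_metric = tc$selection_metric,
                            grid = grid, threshold = tc$threshold,
                            seed = seeds[6])
    tsv(cv$resample_metrics, "resamples.tsv")
    tsv(cv$summary, "cv_summary.tsv")
    tsv(variable_importance(cv$model), "importance.tsv")
    list(cv = cv, part = part)
  })

  ev <- pipeline_stage("evaluate", {
    cm <- evaluate_test(tr$cv$model, feat$matrix[tr$part$test, ],
                        feat$label[tr$part$test],
                        threshold = config$train$threshold)
    cmdf <- data.frame(prediction = c("neutral", "neutral", "PGx", "PGx"),
                       annotation = c("not_annotated", "annotated",
                                      "not_annotated", "annotated"),
                       count = c(cm$tn, cm$fn, cm$fp, cm$tp))
    tsv(cmdf, "confusion.tsv")
    prob <- predict_prob(tr$cv$model, feat$matrix[tr$part$test, ])
    tsv(compute_metrics(cm, config$train$learner,
                        auc = auc(prob, feat$label[tr$part$test])),
        "test_metrics.tsv")
    cm
  })

  pred <- pipeline_stage("predict", {
    annotated <- sim$vt$variants$variant_id[sim$vt$variants$label]
    new_ids <- predict_new(tr$cv$model, feat$matrix, annotated,
                           threshold = config$train$threshold)
    prob <- predict_prob(tr$cv$model, feat$matrix)
    tsv(data.frame(variant_id = rownames(feat$matrix),
                   probability = prob), "predictions.tsv")
    writeLines(new_ids, file.path(out_dir, "predicted_ids.txt"))
    new_ids
  })

  rep_out <- pipeline_stage("report", {
    vn <- venn_partition(sim$vt$pop_af,
                         presence_threshold =
                           config$report$presence_threshold)
    tsv(data.frame(eur_only = vn$eur_only, shared = vn$shared,
                   non_eur_only = vn$non_eur_only, total = vn$total,
                   fraction_non_european =
                     vn$fraction_carried_by_non_europeans), "venn.tsv")
    cc <- counts_by_category(sim$genes, pred, sim$vt$variants)
    tsv(cc$summary, "category_counts.tsv")
    cls <- sim$vt$variants$class
    cls[sim$vt$variants$variant_id %in% pred & cls != "annotated"] <-
      "predicted"
    afc <- af_by_class_population(sim$vt$pop_af, cls)
    tsv(afc, "af_by_class.tsv")
    list(venn = vn, categories = cc, af = afc)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("pgxpredict")),
    r_version = R.version.string,
    seed = config$seed, derived_seeds = seeds,
    config = config[setdiff(names(config), "train")],
    files = as.list(tools::md5sum(list.files(out_dir, full.names = TRUE,
                                             pattern = "\\.(tsv|txt)$"))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(out_dir = out_dir, simulate = sim, enrich = enr,
                 features = feat, train = tr, evaluate = ev,
                 predict = pred, report = rep_out))
}
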