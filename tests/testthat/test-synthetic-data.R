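test_that("generate_genes honors pharmacogene fraction and invariants", {
  g <- generate_genes(100, 0.1, seed = 1)
  expect_equal(sum(g$is_pharmacogene), 10L)
  expect_false(anyDuplicated(g$gene_id) > 0)
  expect_true(all(g$cpic_drug_count[!g$is_pharmacogene] == 0L))
  expect_true(all(g$cpic_drug_count >= 0L))

  # the genome-scale configuration of the real analysis
  g2 <- generate_genes(29521, 1076 / 29521, seed = 2)
  expect_equal(sum(g2$is_pharmacogene), 1076L)

  expect_error(generate_genes(0), class = "pgx_invalid_argument")
})

test_that("generator output is bit-identical under a fixed seed", {
  g1 <- generate_genes(200, 0.1, seed = 9)
  g2 <- generate_genes(200, 0.1, seed = 9)
  expect_identical(g1, g2)
  cfg <- sim_config(n_genes = 200, n_variants = 500, seed = 9)
  v1 <- generate_variant_table(g1, config = cfg)
  v2 <- generate_variant_table(g2, config = cfg)
  expect_identical(v1, v2)
  s1 <- generate_adaptive_signatures(g1, c(a = 50, b = 80), seed = 9)
  expect_identical(s1, generate_adaptive_signatures(g1, c(a = 50, b = 80),
                                                    seed = 9))
})

test_that("variant table has valid structure, classes and AF ranges", {
  w <- tiny_world(seed = 5)
  v <- w$vt$variants
  expect_true(all(PGX_PREDICTORS %in% names(v)))
  expect_true(all(v$gene_id %in% w$genes$gene_id[w$genes$is_pharmacogene]))
  expect_identical(v$label, v$class == "annotated")
  expect_true(all(v$maf >= 0 & v$maf <= 1))
  expect_true(all(v$evo_rate >= 0 & v$evo_rate <= 57405))
  expect_true(all(v$evo_time >= 0 & v$evo_time <= 2774))
  af <- as.matrix(w$vt$pop_af[, -1])
  expect_equal(ncol(af), 26L)
  expect_true(all(af >= 0 & af <= 1))
  expect_identical(colnames(af), population_panel()$label)

  # class counts match the mixture within multinomial error (~4 sd)
  n <- nrow(v)
  probs <- sim_config()$class_probs
  for (cl in names(probs)) {
    expected <- n * probs[[cl]]
    tol <- 4 * sqrt(n * probs[[cl]] * (1 - probs[[cl]]))
    expect_lt(abs(sum(v$class == cl) - expected), tol)
  }

  expect_error(generate_variant_table(w$genes[0, ]),
               class = "pgx_invalid_argument")
  no_pgx <- w$genes
  no_pgx$is_pharmacogene <- FALSE
  expect_error(generate_variant_table(no_pgx),
               class = "pgx_invalid_argument")
})

test_that("zero divergence collapses population AFs onto the global MAF", {
  cfg <- sim_config(n_genes = 100, pgx_fraction = 0.2, n_variants = 300,
                    divergence_fst = 0, african_shift = 0, seed = 3)
  genes <- generate_genes(100, 0.2, seed = 3)
  vt <- generate_variant_table(genes, config = cfg)
  for (lab in population_panel()$label)
    expect_identical(vt$pop_af[[lab]], vt$variants$maf)
})

test_that("Balding-Nichols draws respect fixed endpoints", {
  p <- c(0, 0.2, 1, 0.8, 0)
  out <- withr::with_seed(1, pgxpredict:::balding_nichols(p, 0.2))
  expect_identical(out[c(1, 3, 5)], c(0, 1, 0))
  expect_true(all(out >= 0 & out <= 1))
})

test_that("label-independent configuration decouples label and predictors", {
  cfg <- null_sim_config(n_genes = 500, pgx_fraction = 0.1,
                         n_variants = 20000, seed = 11)
  genes <- generate_genes(500, 0.1, seed = 11)
  vt <- generate_variant_table(genes, config = cfg)
  y <- as.numeric(vt$variants$label)
  for (col in PGX_PREDICTORS) {
    v <- vt$variants[[col]]
    if (stats::sd(v) == 0) next
    expect_lt(abs(stats::cor(y, v)), 0.05)
  }
})

test_that("functional classes are commoner than neutral in every replicate", {
  for (seed in 1:10) {
    cfg <- sim_config(n_genes = 200, n_variants = 3000, seed = seed)
    genes <- generate_genes(200, 0.05, seed = seed)
    v <- generate_variant_table(genes, config = cfg)$variants
    med <- tapply(v$maf, v$class, median)
    expect_gt(med[["annotated"]], med[["neutral"]])
    expect_gt(med[["predicted"]], med[["neutral"]])
  }
})

test_that("adaptive signatures: sizes, exhaustive draw, errors", {
  genes <- generate_genes(29521, 1076 / 29521, seed = 4)
  sigs <- generate_adaptive_signatures(
    genes, c(iHS = 9593, `XP-CLR` = 8636, D = 17734), seed = 4)
  expect_identical(lengths(sigs), c(iHS = 9593L, `XP-CLR` = 8636L,
                                    D = 17734L))
  for (s in sigs) expect_false(anyDuplicated(s) > 0)

  small <- generate_genes(50, 0.2, seed = 1)
  all_of_it <- generate_adaptive_signatures(small, c(x = 50), seed = 1)
  expect_setequal(all_of_it$x, small$gene_id)
  expect_error(generate_adaptive_signatures(small, c(x = 51)),
               class = "pgx_invalid_argument")
})

test_that("uniform signature draws have hypergeometric mean overlap", {
  n_genes <- 500L; k <- 50L; m <- 100L
  genes <- generate_genes(n_genes, k / n_genes, seed = 2)
  pgx <- genes$gene_id[genes$is_pharmacogene]
  draws <- 200L
  overlaps <- vapply(seq_len(draws), function(i) {
    s <- generate_adaptive_signatures(genes, c(x = m),
                                      enrichment_factor = 1, seed = 1000 + i)
    observed_overlap(s$x, pgx)
  }, integer(1))
  expected <- m * k / n_genes
  hyper_var <- m * (k / n_genes) * (1 - k / n_genes) *
    (n_genes - m) / (n_genes - 1)
  se_mean <- sqrt(hyper_var / draws)
  expect_lt(abs(mean(overlaps) - expected), 3 * se_mean)
})
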