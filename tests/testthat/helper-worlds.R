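# Shared fixture builders; everything is generated in code at test time.

# a small but non-trivial labeled world
tiny_world <- function(seed = 42L, n_genes = 300L, n_variants = 1500L) {
  genes <- generate_genes(n_genes, 0.1, seed = seed)
  cfg <- sim_config(n_genes = n_genes, pgx_fraction = 0.1,
                    n_variants = n_variants, seed = seed + 1L)
  vt <- generate_variant_table(genes, config = cfg)
  mm <- model_matrix_from_variants(vt$variants)
  list(genes = genes, vt = vt, x = mm$matrix, y = mm$label)
}

# linearly separable two-class data (one informative coordinate);
# 30% positive so the PGx class is the SMOTE minority, as in real use
separable_data <- function(n = 400L, p = 4L, seed = 1L) {
  set.seed(seed)
  y <- seq_len(n) %% 10 < 3
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  x[, 1] <- ifelse(y, 1, 0) + runif(n, 0, 0.4)   # gap at 0.4..1.0
  list(x = x, y = y)
}

# exhaustive pair-counting AUC oracle (ties count 1/2)
auc_oracle <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (sp in pos) tot <- tot + sum(sp > neg) + 0.5 * sum(sp == neg)
  tot / (length(pos) * length(neg))
}

write_bed <- function(lines) {
  f <- tempfile(fileext = ".bed")
  writeLines(lines, f)
  f
}
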