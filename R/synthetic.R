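#' Simulation configuration for the synthetic variant world
#'
#' Encodes the statistical structure the analysis assumes: three variant
#' classes (`annotated` PGx, `predicted` = functional but not yet annotated,
#' `neutral`), class-specific minor-allele-frequency and feature
#' distributions, and a Balding-Nichols model of per-population
#' allele-frequency divergence around the global frequency.
#'
#' Functional classes default to common variants (MAF ~ Beta(2, 5)) and
#' frequent candidate-adaptive-polymorphism (CAP) status (0.4), neutral
#' variants to rare (MAF ~ Beta(0.5, 20)) and infrequent CAP (0.05). These
#' magnitudes are deliberate artifact choices (the real-world effect sizes
#' are unknown); they are the documented defaults the test-suite world uses.
#'
#' @param n_genes number of genes in the simulated universe.
#' @param pgx_fraction fraction of genes flagged as pharmacogenes.
#' @param n_variants number of missense variants (all placed in
#'   pharmacogenes, as in the real analysis).
#' @param class_probs named mixture proportions over
#'   `c("annotated", "predicted", "neutral")`; must sum to 1.
#' @param maf_beta named list of `c(shape1, shape2)` Beta parameters of the
#'   global-MAF distribution per class.
#' @param cap_prob named per-class probability that the position carries a
#'   candidate adaptive polymorphism.
#' @param divergence_fst Balding-Nichols divergence parameter in `[0, 1)`;
#'   0 makes every population frequency equal the global frequency.
#' @param african_shift additive logit-scale inflation of the global
#'   frequency in AFR panels, applied to the `predicted` class only
#'   (emulating the modest African-panel excess of newly predicted variants).
#' @param seed integer seed making the whole generated world reproducible.
#' @return an object of class `pgx_sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 2000L,
                       pgx_fraction = 0.05,
                       n_variants = 20000L,
                       class_probs = c(annotated = 0.03, predicted = 0.07,
                                       neutral = 0.90),
                       maf_beta = list(annotated = c(2, 5),
                                       predicted = c(2, 5),
                                       neutral = c(0.5, 20)),
                       cap_prob = c(annotated = 0.4, predicted = 0.4,
                                    neutral = 0.05),
                       divergence_fst = 0.08,
                       african_shift = 0.3,
                       seed = 1L) {
  classes <- c("annotated", "predicted", "neutral")
  if (!setequal(names(class_probs), classes))
    stop_invalid("class_probs must be named annotated/predicted/neutral")
  class_probs <- class_probs[classes]
  if (abs(sum(class_probs) - 1) > 1e-8)
    stop_invalid("class_probs must sum to 1")
  for (p in class_probs) assert_proportion(p, "class_probs")
  for (p in cap_prob) assert_proportion(p, "cap_prob")
  assert_proportion(divergence_fst, "divergence_fst")
  if (divergence_fst >= 1) stop_invalid("divergence_fst must be < 1")
  if (african_shift < 0) stop_invalid("african_shift must be >= 0")
  cfg <- list(
    n_genes = as.integer(n_genes), pgx_fraction = pgx_fraction,
    n_variants = as.integer(n_variants),
    class_probs = class_probs,
    maf_beta = maf_beta[classes], cap_prob = cap_prob[classes],
    # mildly class-informative nuisance distributions; MAF/CAP carry the
    # dominant signal by design
    ep_ref_beta = list(annotated = c(4, 2), predicted = c(4, 2),
                       neutral = c(8, 2)),
    ep_alt_beta = list(annotated = c(2, 4), predicted = c(2, 4),
                       neutral = c(1, 9)),
    evo_rate_beta = list(annotated = c(1.5, 6), predicted = c(1.5, 6),
                         neutral = c(1, 8)),
    evo_time_beta = list(annotated = c(4, 3), predicted = c(4, 3),
                         neutral = c(2, 5)),
    flag_rates = list(
      annotated = c(topo_domain = 0.20, chain = 0.60, domain = 0.25,
                    helix = 0.15, "repeat" = 0.05, proteome = 0.90,
                    disulfide = 0.04, variants = 0.30),
      predicted = c(topo_domain = 0.20, chain = 0.60, domain = 0.25,
                    helix = 0.15, "repeat" = 0.05, proteome = 0.90,
                    disulfide = 0.04, variants = 0.30),
      neutral   = c(topo_domain = 0.12, chain = 0.55, domain = 0.20,
                    helix = 0.12, "repeat" = 0.04, proteome = 0.88,
                    disulfide = 0.03, variants = 0.28)),
    divergence_fst = divergence_fst, african_shift = african_shift,
    seed = as.integer(seed))
  class(cfg) <- "pgx_sim_config"
  cfg
}

#' Null simulation configuration (label-independent generator)
#'
#' All three classes share identical feature and frequency distributions, so
#' the PGx label carries no signal. Used for calibration and null checks.
#'
#' @inheritParams sim_config
#' @param ... passed on to [sim_config()].
#' @return a `pgx_sim_config`.
#' @export
null_sim_config <- function(seed = 1L, ...) {
  cfg <- sim_config(seed = seed, ...)
  for (fld in c("maf_beta", "ep_ref_beta", "ep_alt_beta", "evo_rate_beta",
                "evo_time_beta", "flag_rates"))
    cfg[[fld]] <- setNames(rep(cfg[[fld]]["annotated"], 3), names(cfg[[fld]]))
  cfg$cap_prob[] <- cfg$cap_prob[["annotated"]]
  cfg$african_shift <- 0
  cfg
}

#' Generate a gene universe with a pharmacogene subset
#'
#' @param n_genes number of genes (>= 1). The real-data analysis assumes a
#'   universe of 29,521 genes of which 1076 are annotated pharmacogenes.
#' @param pgx_fraction fraction of genes flagged as pharmacogenes; exactly
#'   `round(n_genes * pgx_fraction)` genes get the flag.
#' @param drug_count_weights named numeric weights over the number of
#'   clinically annotated (CPIC) drugs per pharmacogene; names are the drug
#'   counts. Non-pharmacogenes always have count 0.
#' @param seed integer seed.
#' @return data.frame with columns `gene_id`, `is_pharmacogene`,
#'   `cpic_drug_count`.
#' @export
generate_genes <- function(n_genes, pgx_fraction = 0.05,
                           drug_count_weights = NULL, seed = 1L) {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 1)
    stop_invalid("n_genes must be a positive integer")
  assert_proportion(pgx_fraction, "pgx_fraction")
  n_genes <- as.integer(n_genes)
  if (is.null(drug_count_weights)) {
    # most pharmacogenes lack clinical (CPIC) annotation; annotated ones fall
    # in the observed drug-count categories, heavy at small counts
    drug_count_weights <- c("0" = 0.55, "1" = 0.18, "2" = 0.09, "3" = 0.05,
                            "4" = 0.04, "5" = 0.03, "6" = 0.02, "7" = 0.015,
                            "12" = 0.01, "21" = 0.005, "22" = 0.005,
                            "36" = 0.003, "60" = 0.002)
  }
  n_pgx <- as.integer(round(n_genes * pgx_fraction))
  with_seed(seed, {
    gene_id <- sprintf("G%05d", seq_len(n_genes))
    is_pgx <- logical(n_genes)
    is_pgx[sample.int(n_genes, n_pgx)] <- TRUE
    counts <- integer(n_genes)
    if (n_pgx > 0) {
      counts[is_pgx] <- as.integer(sample(names(drug_count_weights), n_pgx,
                                          replace = TRUE,
                                          prob = drug_count_weights))
    }
    data.frame(gene_id = gene_id, is_pharmacogene = is_pgx,
               cpic_drug_count = counts, stringsAsFactors = FALSE)
  })
}

# Balding-Nichols draw of a population frequency around global frequency p:
# Beta(p(1-F)/F, (1-p)(1-F)/F). F = 0 degenerates to p itself; p in {0, 1}
# is fixed (a monomorphic site cannot diverge).
balding_nichols <- function(p, fst) {
  if (fst == 0) return(p)
  out <- p
  poly <- p > 0 & p < 1
  if (any(poly)) {
    k <- (1 - fst) / fst
    out[poly] <- rbeta(sum(poly), p[poly] * k, (1 - p[poly]) * k)
  }
  out
}

#' Generate a labeled variant feature table with population frequencies
#'
#' Each variant is assigned to a pharmacogene, given a class
#' (annotated / predicted / neutral) from the configured mixture, a global
#' MAF from its class's Beta distribution, the 14 model predictors, and 26
#' per-population non-reference allele frequencies drawn from a
#' Balding-Nichols distribution around the global frequency.
#'
#' @param genes gene table from [generate_genes()]; must contain at least
#'   one pharmacogene.
#' @param n_variants number of variants; defaults to the config value.
#' @param config a [sim_config()] object.
#' @return list with `variants` (one row per variant: `variant_id`,
#'   `gene_id`, `class`, `label`, and the 14 predictors in canonical order)
#'   and `pop_af` (`variant_id` plus one allele-frequency column per panel
#'   code).
#' @export
generate_variant_table <- function(genes, n_variants = NULL,
                                   config = sim_config()) {
  if (!is.data.frame(genes) || nrow(genes) == 0L)
    stop_invalid("genes must be a non-empty gene table")
  pgx_genes <- genes$gene_id[genes$is_pharmacogene]
  if (length(pgx_genes) == 0L)
    stop_invalid("gene universe contains no pharmacogene")
  n <- as.integer(n_variants %||% config$n_variants)
  if (n < 1) stop_invalid("n_variants must be positive")
  panel <- population_panel()
  afr <- panel$label[panel$super_group == "AFR"]
  classes <- c("annotated", "predicted", "neutral")

  with_seed(config$seed, {
    cls <- sample(classes, n, replace = TRUE, prob = config$class_probs)
    gene_id <- sample(pgx_genes, n, replace = TRUE)
    draw_beta <- function(par_list, scale = 1) {
      out <- numeric(n)
      for (cl in classes) {
        idx <- cls == cl
        if (any(idx)) {
          par <- par_list[[cl]]
          out[idx] <- rbeta(sum(idx), par[1], par[2]) * scale
        }
      }
      out
    }
    draw_bern <- function(rate_by_class) {
      out <- integer(n)
      for (cl in classes) {
        idx <- cls == cl
        if (any(idx)) out[idx] <- rbinom(sum(idx), 1L, rate_by_class[[cl]])
      }
      out
    }
    maf <- draw_beta(config$maf_beta)
    cap <- draw_bern(config$cap_prob)
    ep_ref <- draw_beta(config$ep_ref_beta)
    ep_alt <- draw_beta(config$ep_alt_beta)
    evo_rate <- draw_beta(config$evo_rate_beta, EVO_RATE_MAX)
    evo_time <- draw_beta(config$evo_time_beta, EVO_TIME_MAX)
    flags <- sapply(PGX_UNIPROT_TRACKS, function(tr)
      draw_bern(lapply(config$flag_rates, `[[`, tr)))

    variants <- data.frame(
      variant_id = sprintf("var%06d", seq_len(n)),
      gene_id = gene_id, class = cls, label = cls == "annotated",
      maf = maf, cap = cap, evo_time = evo_time, ep_alt = ep_alt,
      topo_domain = flags[, "topo_domain"], evo_rate = evo_rate,
      chain = flags[, "chain"], ep_ref = ep_ref, domain = flags[, "domain"],
      helix = flags[, "helix"], "repeat" = flags[, "repeat"],
      proteome = flags[, "proteome"], disulfide = flags[, "disulfide"],
      variants = flags[, "variants"],
      stringsAsFactors = FALSE, check.names = FALSE)

    af <- matrix(0, nrow = n, ncol = nrow(panel),
                 dimnames = list(NULL, panel$label))
    shift_idx <- cls == "predicted"
    for (j in seq_len(nrow(panel))) {
      lab <- panel$label[j]
      p <- maf
      if (config$african_shift > 0 && lab %in% afr) {
        p[shift_idx] <- plogis(qlogis(pmin(pmax(p[shift_idx], 1e-12),
                                           1 - 1e-12)) +
                               config$african_shift)
        p[shift_idx & maf == 0] <- 0
      }
      af[, j] <- balding_nichols(p, config$divergence_fst)
    }
    pop_af <- data.frame(variant_id = variants$variant_id, af,
                         stringsAsFactors = FALSE, check.names = FALSE)
    list(variants = variants, pop_af = pop_af)
  })
}

#' Generate adaptive-signature gene sets
#'
#' Draws one gene-id set per selection-scan statistic, without replacement,
#' optionally enriched for pharmacogenes via a sampling-weight multiplier.
#' Real-data loci counts are 9593 (iHS), 8636 (XP-CLR) and 17,734 (D) out of
#' 29,521 genes; the default sizes scale those proportions to the universe.
#'
#' @param genes gene table from [generate_genes()].
#' @param sizes_by_statistic named integer vector of set sizes; each must
#'   not exceed the universe size.
#' @param enrichment_factor sampling-weight multiplier for pharmacogenes;
#'   1 gives uniform sampling (the null).
#' @param seed integer seed.
#' @return named list mapping statistic name to a character vector of
#'   gene ids.
#' @export
generate_adaptive_signatures <- function(genes, sizes_by_statistic = NULL,
                                         enrichment_factor = 1, seed = 1L) {
  n_genes <- nrow(genes)
  if (is.null(sizes_by_statistic)) {
    sizes_by_statistic <- round(c(iHS = 9593, `XP-CLR` = 8636, D = 17734) *
                                n_genes / 29521)
  }
  if (enrichment_factor < 0) stop_invalid("enrichment_factor must be >= 0")
  if (any(sizes_by_statistic > n_genes))
    stop_invalid("signature size exceeds the gene universe (",
                 n_genes, " genes)")
  w <- ifelse(genes$is_pharmacogene, enrichment_factor, 1)
  seeds <- derive_seeds(seed, length(sizes_by_statistic))
  out <- lapply(seq_along(sizes_by_statistic), function(i) {
    with_seed(seeds[i], {
      m <- as.integer(sizes_by_statistic[i])
      if (m == n_genes) genes$gene_id
      else genes$gene_id[sample.int(n_genes, m, prob = w)]
    })
  })
  names(out) <- names(sizes_by_statistic)
  out
}
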