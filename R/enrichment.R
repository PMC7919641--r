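#' Observed overlap between a signature set and the pharmacogene set
#'
#' @param signature_set,pharmacogene_set character vectors of gene ids drawn
#'   from the same namespace.
#' @return integer cardinality of the intersection.
#' @export
observed_overlap <- function(signature_set, pharmacogene_set) {
  length(intersect(signature_set, pharmacogene_set))
}

#' Permutation enrichment test of pharmacogenes among adaptive signatures
#'
#' Re-draws the signature set `n_permutations` times without replacement
#' from the gene universe, recording the pharmacogene overlap of each draw.
#' The permutation p-value is the inclusive upper tail
#' `(# null overlaps >= observed) / n_permutations`; a complementary
#' empirical p-value standardizes the observed overlap against the
#' permutation null and takes the upper normal tail (see
#' [empirical_p_normal()]).
#'
#' Only pharmacogene *membership* matters under uniform sampling, so the
#' permutation draws indices from `1..universe_size` with the first
#' `length(pharmacogene_set)` indices marked as pharmacogenes; each
#' permutation costs O(signature_size).
#'
#' @param universe_size total number of genes assumed for the permutation.
#' @param pharmacogene_set character vector (or count) of pharmacogenes in
#'   the universe.
#' @param signature_size number of genes drawn per permutation.
#' @param observed the observed overlap (see [observed_overlap()]).
#' @param n_permutations number of permutations (default 1000).
#' @param seed integer seed.
#' @param statistic_name label carried into the result.
#' @return object of class `pgx_enrichment` with fields `statistic_name`,
#'   `observed_overlap`, `n_permutations`, `null_overlaps`, `null_mean`,
#'   `null_sd`, `p_permutation`, `p_empirical_normal`.
#' @export
permutation_enrichment <- function(universe_size, pharmacogene_set,
                                   signature_size, observed,
                                   n_permutations = 1000L, seed = 1L,
                                   statistic_name = "statistic") {
  universe_size <- as.integer(universe_size)
  k <- if (is.numeric(pharmacogene_set) && length(pharmacogene_set) == 1L)
    as.integer(pharmacogene_set) else length(unique(pharmacogene_set))
  if (k > universe_size)
    stop_invalid("more pharmacogenes than genes in the universe")
  signature_size <- as.integer(signature_size)
  if (signature_size > universe_size)
    stop_invalid("signature_size (", signature_size,
                 ") exceeds universe_size (", universe_size, ")")
  if (n_permutations < 1) stop_invalid("n_permutations must be >= 1")
  null_overlaps <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      sum(sample.int(universe_size, signature_size) <= k)
    }, integer(1))
  })
  null_mean <- mean(null_overlaps)
  null_sd <- stats::sd(null_overlaps)
  p_perm <- sum(null_overlaps >= observed) / n_permutations
  p_norm <- if (is.na(null_sd) || null_sd == 0) NA_real_
            else empirical_p_normal(observed, null_mean, null_sd)
  structure(list(statistic_name = statistic_name,
                 observed_overlap = as.integer(observed),
                 n_permutations = as.integer(n_permutations),
                 null_overlaps = null_overlaps,
                 null_mean = null_mean, null_sd = null_sd,
                 p_permutation = p_perm, p_empirical_normal = p_norm),
            class = "pgx_enrichment")
}

#' Upper-tail normal empirical p-value for an observed overlap
#'
#' Standardizes `observed` against the permutation null and returns the
#' upper-tail standard-normal probability of
#' `z = (observed - null_mean) / null_sd` (the directional, enrichment
#' alternative).
#'
#' @param observed observed overlap.
#' @param null_mean,null_sd mean and standard deviation of the permutation
#'   null; `null_sd` must be positive.
#' @return a probability.
#' @export
empirical_p_normal <- function(observed, null_mean, null_sd) {
  assert_scalar_number(null_sd, "null_sd")
  if (null_sd <= 0)
    stop(errorCondition("degenerate null: null_sd must be > 0",
                        class = c("pgx_degenerate_null", "error")))
  pnorm((observed - null_mean) / null_sd, lower.tail = FALSE)
}

# "p < 1/n" convention for a zero permutation count; the stored value is 0.
format_p <- function(p, n_permutations) {
  ifelse(p == 0, sprintf("< %.3g", 1 / n_permutations), sprintf("%.4g", p))
}

#' Run the enrichment test for several signature sets
#'
#' @param universe_size assumed total gene count.
#' @param pharmacogene_set character vector of pharmacogene ids.
#' @param signature_sets named list of gene-id vectors (one per statistic).
#' @param n_permutations permutations per statistic.
#' @param seed master seed (one sub-seed per statistic).
#' @return data.frame with one row per statistic: `statistic`, `observed`,
#'   `null_mean`, `null_sd`, `p_permutation`, `p_permutation_label`,
#'   `p_empirical_normal`.
#' @export
enrichment_test <- function(universe_size, pharmacogene_set, signature_sets,
                            n_permutations = 1000L, seed = 1L) {
  stopifnot(is.list(signature_sets), length(signature_sets) >= 1L)
  seeds <- derive_seeds(seed, length(signature_sets))
  rows <- lapply(seq_along(signature_sets), function(i) {
    sig <- signature_sets[[i]]
    obs <- observed_overlap(sig, pharmacogene_set)
    res <- permutation_enrichment(universe_size, pharmacogene_set,
                                  length(sig), obs, n_permutations,
                                  seed = seeds[i],
                                  statistic_name = names(signature_sets)[i])
    data.frame(statistic = res$statistic_name, observed = res$observed_overlap,
               null_mean = res$null_mean, null_sd = res$null_sd,
               p_permutation = res$p_permutation,
               p_permutation_label = format_p(res$p_permutation,
                                              n_permutations),
               p_empirical_normal = res$p_empirical_normal,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.pgx_enrichment <- function(x, ...) {
  cat("Permutation enrichment:", x$statistic_name, "\n")
  cat(sprintf("  observed overlap: %d (null %.2f +/- %.2f, %d permutations)\n",
              x$observed_overlap, x$null_mean, x$null_sd, x$n_permutations))
  cat(sprintf("  p (permutation) %s; p (normal) %.3g\n",
              format_p(x$p_permutation, x$n_permutations),
              x$p_empirical_normal))
  invisible(x)
}
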