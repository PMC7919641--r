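#' European / non-European presence partition
#'
#' A variant is "present" in a group of panels iff its non-reference allele
#' frequency exceeds `presence_threshold` in at least one panel of the
#' group. Variants absent everywhere are excluded from the partition.
#'
#' @param pop_af_table data.frame `variant_id` plus one AF column per panel
#'   code; must cover all panels of `panel`.
#' @param panel population panel (default [population_panel()]); EUR
#'   membership comes from its `super_group` column.
#' @param presence_threshold presence rule: AF strictly greater than this
#'   value (default 0, i.e. any observed copy).
#' @return object of class `pgx_venn` with `eur_only`, `non_eur_only`,
#'   `shared`, `total` and `fraction_carried_by_non_europeans` =
#'   `(shared + non_eur_only) / total`.
#' @export
venn_partition <- function(pop_af_table, panel = population_panel(),
                           presence_threshold = 0) {
  missing_cols <- setdiff(panel$label, names(pop_af_table))
  if (length(missing_cols))
    stop_invalid("AF table lacks panel columns: ",
                 paste(missing_cols, collapse = ", "))
  eur <- panel_labels(panel, "EUR")
  non_eur <- setdiff(panel$label, eur)
  af_eur <- as.matrix(pop_af_table[, eur, drop = FALSE])
  af_non <- as.matrix(pop_af_table[, non_eur, drop = FALSE])
  in_eur <- rowSums(af_eur > presence_threshold) > 0
  in_non <- rowSums(af_non > presence_threshold) > 0
  seg <- in_eur | in_non
  res <- list(eur_only = sum(in_eur & !in_non),
              non_eur_only = sum(!in_eur & in_non),
              shared = sum(in_eur & in_non),
              total = sum(seg))
  res$fraction_carried_by_non_europeans <-
    if (res$total == 0) NA_real_
    else (res$shared + res$non_eur_only) / res$total
  structure(res, class = "pgx_venn")
}

#' @export
print.pgx_venn <- function(x, ...) {
  cat(sprintf(paste0("Segregating variants: %d (EUR-only %d | shared %d | ",
                     "non-EUR-only %d)\n"),
              x$total, x$eur_only, x$shared, x$non_eur_only))
  cat(sprintf("Fraction carried by non-Europeans: %.3f\n",
              x$fraction_carried_by_non_europeans))
  invisible(x)
}

#' Newly-predicted variant counts by CPIC drug-count category
#'
#' Groups pharmacogenes into bins of their clinically annotated drug count
#' and collects, per bin, the per-gene counts of newly predicted variants.
#' Default bins are unit bins over the observed drug counts.
#'
#' @param gene_table gene table (`gene_id`, `is_pharmacogene`,
#'   `cpic_drug_count`).
#' @param predicted_set character vector of newly predicted variant ids.
#' @param variant_table data.frame mapping `variant_id` to `gene_id`.
#' @param bins optional named list of integer vectors of drug counts; must
#'   partition the observed counts (no overlaps).
#' @return object of class `pgx_category_counts`: a list with `bins` and
#'   `per_gene` (data.frame `gene_id`, `cpic_drug_count`, `bin`,
#'   `n_predicted`), plus a `summary` data.frame per bin.
#' @export
counts_by_category <- function(gene_table, predicted_set, variant_table,
                               bins = NULL) {
  pgx <- gene_table[gene_table$is_pharmacogene, , drop = FALSE]
  observed <- sort(unique(pgx$cpic_drug_count))
  if (is.null(bins)) {
    bins <- lapply(observed, identity)
    names(bins) <- as.character(observed)
  }
  allv <- unlist(bins)
  if (anyDuplicated(allv))
    stop_invalid("bins overlap: drug count ",
                 allv[duplicated(allv)][1], " appears twice")
  if (!all(observed %in% allv))
    stop_invalid("bins do not cover observed drug counts: ",
                 paste(setdiff(observed, allv), collapse = ", "))
  bin_of <- function(ct) names(bins)[vapply(bins, function(b) ct %in% b,
                                            logical(1))][1]
  pred_gene <- variant_table$gene_id[variant_table$variant_id %in%
                                       predicted_set]
  tab <- table(pred_gene)
  per_gene <- data.frame(
    gene_id = pgx$gene_id,
    cpic_drug_count = pgx$cpic_drug_count,
    bin = vapply(pgx$cpic_drug_count, bin_of, ""),
    n_predicted = as.integer(tab[pgx$gene_id]),
    stringsAsFactors = FALSE)
  per_gene$n_predicted[is.na(per_gene$n_predicted)] <- 0L
  summ <- do.call(rbind, lapply(names(bins), function(b) {
    v <- per_gene$n_predicted[per_gene$bin == b]
    data.frame(bin = b, n_genes = length(v),
               total_predicted = sum(v),
               median_predicted = if (length(v)) median(v) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(bins = bins, per_gene = per_gene, summary = summ),
            class = "pgx_category_counts")
}

#' Allele-frequency summaries by variant class and population
#'
#' Long-format five-number summaries of the non-reference allele frequency
#' for each (population panel, variant class) cell — the table behind the
#' class-stratified boxplots.
#'
#' @param pop_af_table data.frame `variant_id` plus one AF column per panel.
#' @param class_assignment character vector (or factor) assigning each row
#'   of `pop_af_table` to exactly one class (`annotated`, `predicted`,
#'   `neutral`, ...).
#' @param panel population panel.
#' @return data.frame with one row per (population, class): `population`,
#'   `class`, `n`, `min`, `q1`, `median`, `q3`, `max`.
#' @export
af_by_class_population <- function(pop_af_table, class_assignment,
                                   panel = population_panel()) {
  if (length(class_assignment) != nrow(pop_af_table))
    stop_invalid("class_assignment length mismatch")
  classes <- unique(as.character(class_assignment))
  rows <- list()
  for (lab in panel$label) {
    afv <- pop_af_table[[lab]]
    if (is.null(afv)) stop_invalid("unknown population label: ", lab)
    for (cl in classes) {
      v <- afv[class_assignment == cl]
      q <- quantile(v, c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
      rows[[length(rows) + 1L]] <-
        data.frame(population = lab, class = cl, n = length(v),
                   min = q[1], q1 = q[2], median = q[3], q3 = q[4],
                   max = q[5], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
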