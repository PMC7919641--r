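#' SMOTE configuration
#'
#' Defaults (k = 5, 200% oversampling, 200% undersampling) match the
#' conventional wrapped implementation's defaults.
#'
#' @param k_neighbors number of nearest minority neighbors to interpolate
#'   towards.
#' @param perc_over oversampling percentage; `perc_over %/% 100` synthetic
#'   points are created per minority point.
#' @param perc_under undersampling percentage; `perc_under / 100 *
#'   n_synthetic` majority points are retained.
#' @param standardize if `TRUE`, columns are standardized before distance
#'   computation (off by default, matching the wrapped implementation).
#' @param seed integer seed.
#' @return object of class `pgx_smote_config`.
#' @export
smote_config <- function(k_neighbors = 5L, perc_over = 200, perc_under = 200,
                         standardize = FALSE, seed = 1L) {
  if (k_neighbors < 1) stop_invalid("k_neighbors must be >= 1")
  if (perc_over < 100) stop_invalid("perc_over must be >= 100")
  structure(list(k_neighbors = as.integer(k_neighbors),
                 perc_over = perc_over, perc_under = perc_under,
                 standardize = isTRUE(standardize),
                 seed = as.integer(seed)),
            class = "pgx_smote_config")
}

# k nearest minority neighbors of each minority row (self excluded),
# Euclidean distance over all columns, ties broken by lowest row index.
smote_neighbors <- function(xm, k) {
  n <- nrow(xm)
  kk <- min(k, n - 1L)
  d2 <- as.matrix(stats::dist(xm))^2
  out <- matrix(0L, n, kk)
  for (i in seq_len(n)) {
    ord <- order(d2[i, ], seq_len(n))  # distance, then row index
    ord <- ord[ord != i]
    out[i, ] <- ord[seq_len(kk)]
  }
  out
}

#' SMOTE: synthetic minority oversampling with majority undersampling
#'
#' For each minority point, `perc_over %/% 100` synthetic points are created
#' at `x + u (x_nn - x)` with `u ~ Uniform(0, 1)` and `x_nn` one of its
#' `k_neighbors` nearest minority neighbors (Euclidean distance over all
#' columns, binary flags as 0/1). Binary columns of a synthetic point copy
#' the parent's or the neighbor's value, chosen uniformly per column. The
#' majority class is then downsampled to `perc_under / 100` times the number
#' of synthetic points.
#'
#' @param x numeric matrix of predictors.
#' @param labels logical (or two-level) class labels; the rarer level is the
#'   minority class.
#' @param config a [smote_config()].
#' @param binary_cols names or indices of binary columns; auto-detected
#'   (columns containing only 0/1) when `NULL`.
#' @return list with `x` (balanced matrix), `labels` (same encoding as the
#'   input; synthetic points carry the minority label), and `provenance` —
#'   a list holding, for each synthetic point,
#'   its parent and neighbor row indices into the *input* matrix, the
#'   interpolation draw `u`, plus the retained original minority and
#'   majority row indices.
#' @export
smote_sample <- function(x, labels, config = smote_config(),
                         binary_cols = NULL) {
  x <- as.matrix(x)
  if (is.factor(labels)) labels <- as.character(labels)
  lv <- unique(labels)
  if (length(lv) != 2L)
    stop_invalid("smote_sample requires exactly two classes, got ",
                 length(lv))
  counts <- table(labels)
  minority_level <- names(counts)[which.min(counts)]
  is_min <- labels == minority_level
  min_idx <- which(is_min)
  maj_idx <- which(!is_min)
  n_min <- length(min_idx)
  if (is.null(binary_cols)) {
    binary_cols <- which(apply(x, 2, function(cc) all(cc %in% c(0, 1))))
  } else if (is.character(binary_cols)) {
    binary_cols <- match(binary_cols, colnames(x))
  }
  cont_cols <- setdiff(seq_len(ncol(x)), binary_cols)

  n_per <- config$perc_over %/% 100
  n_syn <- n_min * n_per
  xm <- x[min_idx, , drop = FALSE]
  if (config$standardize) {
    sdv <- apply(xm, 2, stats::sd)
    sdv[sdv == 0] <- 1
    xs <- sweep(xm, 2, sdv, "/")
  } else xs <- xm

  with_seed(config$seed, {
    if (n_min == 1L) {
      warning("minority class has a single member; synthetic points are copies")
      nn <- matrix(integer(0), nrow = 1L, ncol = 0L)
    } else {
      nn <- smote_neighbors(xs, config$k_neighbors)
    }
    syn <- matrix(NA_real_, nrow = n_syn, ncol = ncol(x),
                  dimnames = list(NULL, colnames(x)))
    parent <- integer(n_syn); neigh <- integer(n_syn); uu <- numeric(n_syn)
    s <- 0L
    for (i in seq_len(n_min)) {
      for (r in seq_len(n_per)) {
        s <- s + 1L
        parent[s] <- min_idx[i]
        if (ncol(nn) == 0L) {       # singleton minority: copy the point
          neigh[s] <- min_idx[i]
          uu[s] <- 0
          syn[s, ] <- xm[i, ]
          next
        }
        j <- nn[i, sample.int(ncol(nn), 1L)]
        neigh[s] <- min_idx[j]
        u <- runif(1)
        uu[s] <- u
        row <- xm[i, ]
        row[cont_cols] <- xm[i, cont_cols] +
          u * (xm[j, cont_cols] - xm[i, cont_cols])
        if (length(binary_cols)) {
          take_nn <- runif(length(binary_cols)) < 0.5
          row[binary_cols] <- ifelse(take_nn, xm[j, binary_cols],
                                     xm[i, binary_cols])
        }
        syn[s, ] <- row
      }
    }
    n_keep <- round(config$perc_under / 100 * n_syn)
    if (n_keep > length(maj_idx)) {
      warning("fewer majority points than requested; keeping all ",
              length(maj_idx))
      n_keep <- length(maj_idx)
    }
    keep_maj <- sort(maj_idx[sample.int(length(maj_idx), n_keep)])
    out_x <- rbind(x[min_idx, , drop = FALSE], syn,
                   x[keep_maj, , drop = FALSE])
    majority_level <- setdiff(names(counts), minority_level)
    out_lab <- c(rep(minority_level, n_min + n_syn),
                 rep(majority_level, n_keep))
    if (is.logical(lv)) out_lab <- as.logical(out_lab)
    rownames(out_x) <- NULL
    list(x = out_x, labels = out_lab,
         provenance = list(parent = parent, neighbor = neigh, u = uu,
                           minority = min_idx, majority_kept = keep_maj,
                           minority_level = minority_level))
  })
}
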