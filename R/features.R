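#' Read BED-style protein-feature tracks
#'
#' Each file becomes one feature track named after the file stem. BED
#' coordinates are 0-based half-open; they are stored as 1-based closed
#' `GRanges`, so downstream overlap with 1-based variant positions needs no
#' further conversion.
#'
#' @param paths character vector of BED file paths (3+ tab-separated
#'   columns; `track`/`browser`/`#` lines and blank lines are skipped).
#' @return named list of `GRanges`, one per file.
#' @export
read_bed_tracks <- function(paths) {
  out <- lapply(paths, function(path) {
    if (!file.exists(path)) stop_invalid("BED file not found: ", path)
    lines <- readLines(path)
    keep <- !grepl("^(#|track\\b|browser\\b)|^\\s*$", lines)
    idx <- which(keep)
    if (length(idx) == 0L)
      return(GenomicRanges::GRanges())
    fields <- strsplit(lines[idx], "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3L))
      stop_invalid(path, " line ", idx[which(nf < 3L)[1]],
                   ": fewer than 3 BED columns")
    chrom <- vapply(fields, `[[`, "", 1L)
    start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
    end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
    bad <- which(is.na(start) | is.na(end))
    if (length(bad))
      stop_invalid(path, " line ", idx[bad[1]],
                   ": non-integer BED coordinates")
    bad <- which(start >= end)
    if (length(bad))
      stop_invalid(path, " line ", idx[bad[1]], ": start >= end (",
                   start[bad[1]], " >= ", end[bad[1]], ")")
    gr <- GenomicRanges::GRanges(chrom,
                                 IRanges::IRanges(start + 1L, end))
    sort(gr)
  })
  names(out) <- sub("\\.bed$", "", basename(paths))
  out
}

#' Encode presence/absence of variants in feature tracks
#'
#' A variant at 1-based position `pos` is "present" in a track iff its
#' 0-based position `pos - 1` falls in some half-open BED interval
#' `[start, end)` of that track on the same chromosome (equivalently, `pos`
#' overlaps the 1-based closed range the track stores).
#'
#' @param variants data.frame with columns `chrom` and `position` (1-based).
#' @param tracks named list of `GRanges` from [read_bed_tracks()].
#' @return integer 0/1 matrix, one row per variant, one column per track.
#' @export
encode_uniprot <- function(variants, tracks) {
  stopifnot(all(c("chrom", "position") %in% names(variants)))
  vr <- GenomicRanges::GRanges(variants$chrom,
                               IRanges::IRanges(variants$position,
                                                variants$position))
  flags <- vapply(tracks, function(tr) {
    as.integer(GenomicRanges::countOverlaps(vr, tr) > 0L)
  }, integer(nrow(variants)))
  if (is.null(dim(flags)))
    flags <- matrix(flags, nrow = nrow(variants),
                    dimnames = list(NULL, names(tracks)))
  rownames(flags) <- variants$variant_id
  flags
}

#' Assemble the 14-predictor model matrix
#'
#' Joins per-variant global MAF, CAP membership, the four evolutionary
#' statistics and the 8 binary feature flags into the canonical model
#' matrix. Variants lacking any evolutionary statistic are dropped (the
#' retention rule of the source analysis); variants with missing MAF are
#' likewise dropped rather than imputed. Every exclusion is recorded in a
#' drop log.
#'
#' @param variants data.frame with a `variant_id` column (ids unique).
#' @param flags 0/1 matrix from [encode_uniprot()] with rownames = variant
#'   ids and one column per track in `PGX_UNIPROT_TRACKS`.
#' @param evo_table data.frame `variant_id`, `ep_ref`, `ep_alt`, `evo_rate`,
#'   `evo_time`.
#' @param cap_set character vector of CAP variant ids.
#' @param maf_table data.frame `variant_id`, `maf`.
#' @return list with `matrix` (rows = retained variants, 14 predictor
#'   columns in canonical order), `variant_id` (retained ids) and `drop_log`
#'   (data.frame `variant_id`, `reason`).
#' @export
assemble_features <- function(variants, flags, evo_table, cap_set,
                              maf_table) {
  for (tb in list(variants, evo_table, maf_table)) {
    if (anyDuplicated(tb$variant_id))
      stop(errorCondition("duplicate variant_id in input table",
                          class = c("pgx_data_integrity", "error")))
  }
  ids <- variants$variant_id
  evo <- evo_table[match(ids, evo_table$variant_id), , drop = FALSE]
  maf <- maf_table$maf[match(ids, maf_table$variant_id)]
  evo_cols <- c("ep_ref", "ep_alt", "evo_rate", "evo_time")
  no_evo <- is.na(evo$variant_id) |
    Reduce(`|`, lapply(evo_cols, function(cc) is.na(evo[[cc]])))
  no_maf <- is.na(maf)
  drop_log <- rbind(
    data.frame(variant_id = ids[no_evo],
               reason = rep("no evolutionary probability", sum(no_evo)),
               stringsAsFactors = FALSE),
    data.frame(variant_id = ids[!no_evo & no_maf],
               reason = rep("no MAF", sum(!no_evo & no_maf)),
               stringsAsFactors = FALSE))
  keep <- !no_evo & !no_maf
  ids_k <- ids[keep]
  fl <- flags[match(ids_k, rownames(flags)), PGX_UNIPROT_TRACKS,
              drop = FALSE]
  fl[is.na(fl)] <- 0L
  m <- cbind(maf = maf[keep],
             cap = as.integer(ids_k %in% cap_set),
             evo_time = evo$evo_time[keep],
             ep_alt = evo$ep_alt[keep],
             topo_domain = fl[, "topo_domain"],
             evo_rate = evo$evo_rate[keep],
             chain = fl[, "chain"],
             ep_ref = evo$ep_ref[keep],
             domain = fl[, "domain"],
             helix = fl[, "helix"],
             "repeat" = fl[, "repeat"],
             proteome = fl[, "proteome"],
             disulfide = fl[, "disulfide"],
             variants = fl[, "variants"])
  colnames(m) <- PGX_PREDICTORS
  rownames(m) <- ids_k
  if (any(m[, "ep_ref"] < 0 | m[, "ep_ref"] > 1) ||
      any(m[, "ep_alt"] < 0 | m[, "ep_alt"] > 1) ||
      any(m[, "maf"] < 0 | m[, "maf"] > 1))
    stop_invalid("proportions outside [0, 1] in assembled features")
  if (any(m[, "evo_rate"] < 0 | m[, "evo_rate"] > EVO_RATE_MAX))
    stop_invalid("evo_rate outside [0, ", EVO_RATE_MAX, "]")
  if (any(m[, "evo_time"] < 0 | m[, "evo_time"] > EVO_TIME_MAX))
    stop_invalid("evo_time outside [0, ", EVO_TIME_MAX, "]")
  list(matrix = m, variant_id = ids_k, drop_log = drop_log)
}

#' Label variants from an annotation id set
#'
#' @param variant_ids character vector of variant ids (or a data.frame with
#'   a `variant_id` column).
#' @param annotated_id_set character vector of annotated PGx variant ids.
#' @return logical vector, `TRUE` iff the id is annotated.
#' @export
label_from_annotations <- function(variant_ids, annotated_id_set) {
  if (is.data.frame(variant_ids)) variant_ids <- variant_ids$variant_id
  variant_ids %in% annotated_id_set
}

#' Extract the model matrix and labels from a synthetic variant table
#'
#' @param variants the `variants` element of [generate_variant_table()].
#' @return list with `matrix` (n x 14, rownames = variant ids) and `label`
#'   (logical).
#' @export
model_matrix_from_variants <- function(variants) {
  m <- as.matrix(variants[, PGX_PREDICTORS])
  rownames(m) <- variants$variant_id
  list(matrix = m, label = variants$label)
}

#' Write / read a model matrix as TSV
#'
#' Values are written with full precision so a round trip reproduces the
#' matrix to better than 1e-12.
#'
#' @param m numeric matrix with rownames (variant ids).
#' @param path TSV path.
#' @return `read_model_matrix` returns the matrix with rownames restored.
#' @export
write_model_matrix <- function(m, path) {
  # %.17g guarantees an exact double round trip through the text file
  dt <- data.table::data.table(variant_id = rownames(m))
  for (cc in colnames(m)) dt[[cc]] <- sprintf("%.17g", m[, cc])
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_model_matrix
#' @export
read_model_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", check.names = FALSE)
  ids <- dt$variant_id
  dt[, variant_id := NULL]
  m <- as.matrix(dt)
  rownames(m) <- ids
  m
}

#' Read variant sites from a (sites-only) VCF
#'
#' Thin wrapper for the optional real-data path; genotypes are not needed.
#'
#' @param path VCF path (uncompressed or bgzipped).
#' @return data.frame `variant_id`, `chrom`, `position`, `ref`, `alt`.
#' @export
read_variant_sites <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop_invalid("reading VCF requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- vapply(as.list(VariantAnnotation::alt(vcf)), function(a)
    as.character(a)[1], "")
  data.frame(variant_id = names(rr),
             chrom = as.character(GenomicRanges::seqnames(rr)),
             position = GenomicRanges::start(rr),
             ref = as.character(VariantAnnotation::ref(vcf)),
             alt = alt, stringsAsFactors = FALSE)
}
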