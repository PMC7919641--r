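test_that("BED tracks parse, with line-numbered errors on malformed input", {
  f <- write_bed(c("chr1\t10\t20\tchain", "chr2\t0\t5"))
  tracks <- read_bed_tracks(f)
  expect_length(tracks, 1L)
  gr <- tracks[[1]]
  expect_equal(length(gr), 2L)
  # 0-based half-open (10, 20) is stored 1-based closed as 11..20
  i <- which(as.character(GenomicRanges::seqnames(gr)) == "chr1")
  expect_equal(GenomicRanges::start(gr)[i], 11L)
  expect_equal(GenomicRanges::end(gr)[i], 20L)

  empty <- write_bed(character(0))
  expect_length(read_bed_tracks(empty)[[1]], 0L)

  inverted <- write_bed("chr1\t20\t10")
  expect_error(read_bed_tracks(inverted), "line 1.*start >= end",
               class = "pgx_invalid_argument")
  bad <- write_bed(c("chr1\t1\t5", "chr1\tx\t9"))
  expect_error(read_bed_tracks(bad), "line 2")
})

test_that("presence encoding respects half-open BED boundaries", {
  f <- write_bed("chr1\t10\t20")
  tracks <- read_bed_tracks(f)
  names(tracks) <- "domain"
  variants <- data.frame(variant_id = paste0("v", 1:4), chrom = "chr1",
                         position = c(11L, 10L, 20L, 21L))
  flags <- encode_uniprot(variants, tracks)
  expect_identical(as.integer(flags[, "domain"]), c(1L, 0L, 1L, 0L))
})

test_that("encode_uniprot agrees with a brute-force interval scan", {
  set.seed(31)
  n_iv <- 800L
  chrom <- sample(c("chr1", "chr2"), n_iv, replace = TRUE)
  start <- sample.int(5000, n_iv, replace = TRUE)
  end <- start + sample.int(50, n_iv, replace = TRUE)
  f <- write_bed(sprintf("%s\t%d\t%d", chrom, start, end))
  tracks <- read_bed_tracks(f)
  names(tracks) <- "trk"
  variants <- data.frame(variant_id = paste0("v", 1:500),
                         chrom = sample(c("chr1", "chr2"), 500, TRUE),
                         position = sample.int(5100, 500, TRUE))
  fast <- encode_uniprot(variants, tracks)[, "trk"]
  brute <- vapply(seq_len(nrow(variants)), function(i) {
    pos0 <- variants$position[i] - 1L
    as.integer(any(chrom == variants$chrom[i] & start <= pos0 & pos0 < end))
  }, integer(1))
  expect_identical(unname(fast), brute)
})

test_that("assemble_features applies the retention rule and orders columns", {
  variants <- data.frame(variant_id = paste0("v", 1:4), stringsAsFactors = FALSE)
  flags <- matrix(0L, 4, 8,
                  dimnames = list(variants$variant_id,
                                  pgxpredict:::PGX_UNIPROT_TRACKS))
  flags["v2", "chain"] <- 1L
  evo <- data.frame(variant_id = c("v1", "v2", "v4"),
                    ep_ref = c(0.9, 0.5, 0.2), ep_alt = c(0.1, 0.4, 0.6),
                    evo_rate = c(3, 57405, 100), evo_time = c(10, 2774, NA))
  maf <- data.frame(variant_id = paste0("v", 1:4),
                    maf = c(0.2, 0.01, 0.3, 0.4))
  out <- assemble_features(variants, flags, evo, cap_set = "v2", maf)
  # v3 lacks all evolutionary statistics, v4 lacks evo_time -> both dropped
  expect_identical(out$variant_id, c("v1", "v2"))
  expect_identical(colnames(out$matrix), PGX_PREDICTORS)
  expect_equal(ncol(out$matrix), 14L)
  expect_setequal(out$drop_log$variant_id, c("v3", "v4"))
  expect_true(all(out$drop_log$reason == "no evolutionary probability"))
  expect_equal(unname(out$matrix["v2", "cap"]), 1)
  expect_equal(unname(out$matrix["v2", "evo_rate"]), 57405)
  expect_equal(unname(out$matrix["v2", "chain"]), 1)

  # missing MAF is an exclusion, not an imputation
  maf_na <- maf; maf_na$maf[1] <- NA
  out2 <- assemble_features(variants, flags, evo, "v2", maf_na)
  expect_identical(out2$variant_id, "v2")
  expect_true("no MAF" %in% out2$drop_log$reason)

  dup <- rbind(variants, variants[1, ])
  expect_error(assemble_features(dup, flags, evo, "v2", maf),
               class = "pgx_data_integrity")
})

test_that("labels come from annotation membership", {
  ids <- paste0("v", 1:10)
  expect_false(any(label_from_annotations(ids, character(0))))
  expect_true(all(label_from_annotations(ids, ids)))
  expect_equal(sum(label_from_annotations(ids, c("v2", "v5", "v9", "zz"))), 3L)
})

test_that("model matrix round-trips through TSV within 1e-12", {
  set.seed(8)
  m <- matrix(runif(60) * rep(c(1, 1e-6, 57405), each = 20), 20, 3,
              dimnames = list(paste0("v", 1:20), c("maf", "ep_alt", "evo_rate")))
  f <- tempfile(fileext = ".tsv")
  write_model_matrix(m, f)
  m2 <- read_model_matrix(f)
  expect_identical(dimnames(m2), dimnames(m))
  expect_lt(max(abs(m2 - m)), 1e-12)
})
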