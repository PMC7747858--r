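# Reliability filters and germline-catalog exclusion.

test_that("quality rule resolves boundary evidence with the stated senses", {
  check <- function(depth, alt, q, vclass, expected) {
    v <- mk_variants(depth = depth, alt_reads = alt, qphred = q,
                     vclass = vclass,
                     ref = if (vclass == "SNV") "C" else "CA",
                     alt = if (vclass == "SNV") "A" else "C")
    expect_identical(passes_quality(v), expected,
                     label = sprintf("depth=%d alt=%d q=%g %s",
                                     depth, alt, q, vclass))
  }
  # depth floor is inclusive at 10
  check(10L, 3L, 20, "SNV", TRUE)
  check(9L, 9L, 60, "SNV", FALSE)   # high VAF cannot rescue low depth
  # read-support floor is inclusive at 3
  check(100L, 3L, 60, "SNV", FALSE) # 3/100 = 3% fails the VAF arm
  check(20L, 2L, 60, "SNV", FALSE)  # 2 reads, 10% fails the read arm
  check(20L, 3L, 60, "SNV", TRUE)   # 3/20 = 15% exactly: inclusive
  check(21L, 3L, 60, "SNV", FALSE)  # 3/21 = 14.3%: below
  # QPHRED floors: 20 for SNVs, 30 for indels
  check(100L, 30L, 20, "SNV", TRUE)
  check(100L, 30L, 19, "SNV", FALSE)
  check(50L, 10L, 30, "indel", TRUE)
  check(50L, 10L, 29, "indel", FALSE)
  # zero depth never passes
  check(0L, 0L, 60, "SNV", FALSE)
})

test_that("germline exclusion is inclusive at 1e-5 and allele-exact", {
  v <- mk_variants(n = 4, chrom = "chr1", pos = c(100L, 200L, 300L, 400L))
  catalog <- mk_catalog(chrom = c("chr1", "chr1", "chr1"),
                        pos = c(100L, 200L, 400L),
                        ref = c("C", "C", "T"), alt = c("A", "A", "G"),
                        frequency = c(1e-5, 9.9e-6, 0.5))
  keep <- exclude_germline(v, catalog)
  expect_identical(keep, c(FALSE,  # frequency exactly 1e-5: excluded
                           TRUE,   # 9.9e-6: strictly below, retained
                           TRUE,   # absent from catalog: retained
                           TRUE))  # position matches but alleles differ
})

test_that("malformed catalogs are rejected with row locations", {
  v <- mk_variants()
  bad <- mk_catalog(chrom = "chr1", pos = 1L, ref = "C", alt = "A",
                    frequency = NA_real_)
  expect_error(exclude_germline(v, bad), "malformed")
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt\tfrequency",
               "chr1\t10\tC\tA\t0.1",
               "chr1\t20\tC\tA\tnot_a_number"), tf)
  expect_error(read_germline_catalog(tf), "lines: 3")
})

test_that("a hand-enumerated 5-variant table attributes attrition per rule", {
  v <- rbind(
    mk_variants(pos = 1L, depth = 100L, alt_reads = 30L, qphred = 60),
    mk_variants(pos = 2L, depth = 9L, alt_reads = 9L, qphred = 60),
    mk_variants(pos = 3L, depth = 50L, alt_reads = 10L, qphred = 29,
                vclass = "indel", ref = "CA", alt = "C"),
    mk_variants(pos = 4L, depth = 100L, alt_reads = 40L, qphred = 60),
    mk_variants(pos = 5L, depth = 20L, alt_reads = 3L, qphred = 20))
  catalog <- mk_catalog(chrom = "chr1", pos = 4L, ref = "C", alt = "A",
                        frequency = 1e-3)
  res <- qc_pipeline(v, qc_thresholds(), catalog)
  expect_identical(res$attrition, c(quality = 2L, germline = 1L))
  expect_identical(res$variants$pos, c(1L, 5L))
})

test_that("qc_pipeline is idempotent, partitions input, passes all-good input", {
  co <- generate_cohort(small_cohort_config(seed = 21, n_patients = 1))
  v <- co$variants$P1_primary
  res1 <- qc_pipeline(v, qc_thresholds(), co$germline)
  res2 <- qc_pipeline(res1$variants, qc_thresholds(), co$germline)
  expect_identical(res2$variants, res1$variants)
  expect_identical(unname(res2$attrition), c(0L, 0L))
  # partition: retained + removed = input
  expect_identical(nrow(res1$variants) + sum(res1$attrition), nrow(v))
  # an all-passing table comes through identical
  good <- mk_variants(n = 10, pos = 1:10)
  res3 <- qc_pipeline(good, qc_thresholds(), empty_catalog())
  expect_identical(res3$variants, good)
  # empty input: empty output, zero attrition, no error
  res4 <- qc_pipeline(good[0, ], qc_thresholds(), empty_catalog())
  expect_identical(nrow(res4$variants), 0L)
  expect_identical(unname(res4$attrition), c(0L, 0L))
})

test_that("raising any threshold never enlarges the retained set", {
  set.seed(31)
  v <- mk_variants(n = 200, pos = 1:200,
                   depth = sample(5:60, 200, TRUE),
                   alt_reads = 0L, qphred = sample(10:40, 200, TRUE))
  v$alt_reads <- vapply(v$depth, function(d) sample.int(d + 1L, 1L) - 1L,
                        integer(1))
  base <- qc_thresholds()
  kept0 <- which(passes_quality(v, base))
  bump <- list(min_depth = 15, min_alt_reads = 5, min_vaf = 0.25,
               min_qphred_snv = 30, min_qphred_indel = 40)
  for (nm in names(bump)) {
    args <- stats::setNames(list(bump[[nm]]), nm)
    kept <- which(passes_quality(v, do.call(qc_thresholds, args)))
    expect_true(all(kept %in% kept0), label = paste("monotone in", nm))
  }
})

test_that("germline-origin variants are fully removed on separable cohorts", {
  co <- generate_cohort(small_cohort_config(seed = 41, n_patients = 2))
  for (s in names(co$variants)) {
    pid <- sub("_(primary|met)$", "", s)
    res <- qc_pipeline(co$variants[[s]], qc_thresholds(), co$germline)
    kept_ids <- paste(pid, res$variants$chrom, res$variants$pos,
                      res$variants$ref, res$variants$alt, sep = ":")
    gl <- co$truth$variant_id[co$truth$origin == "germline"]
    expect_length(intersect(kept_ids, gl), 0L)
  }
})
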