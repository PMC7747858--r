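# Coverage log ratios, CBS segmentation, zero level, state calling, and
# cross-patient recurrence.

test_that("log ratios are zero for identical coverage and follow doublings", {
  p <- mk_coverage(rep(100, 50))
  expect_equal(log_ratio(p, p)$log2_ratio, rep(0, 50))
  m <- p
  m$depth[10] <- 200
  m$depth[20:21] <- 50  # keep totals equal: +100 -100
  lr <- log_ratio(p, m)
  expect_equal(lr$log2_ratio[10], 1.0)
  expect_equal(lr$log2_ratio[1], 0)
  # masking: low primary depth and zero met depth
  p2 <- p; p2$depth[5] <- 9
  m2 <- p; m2$depth[7] <- 0
  expect_true(is.na(log_ratio(p2, p)$log2_ratio[5]))
  expect_true(is.na(log_ratio(p, m2)$log2_ratio[7]))
  # mismatched grids are an error
  expect_error(log_ratio(p, p[-1, ]), "grid")
})

test_that("noise-free planted segments reproduce their log ratio exactly", {
  cfg <- small_cohort_config(
    seed = 6, n_patients = 1, bin_noise_sd = 0,
    planted_segments = data.frame(chrom = "chr2", start_bin = 100L,
                                  end_bin = 149L, log2_ratio = 0.6))
  co <- generate_cohort(cfg)
  p <- co$coverage$P1_primary
  m <- co$coverage$P1_met
  raw <- log_ratio(p, m, normalize = FALSE)
  sel <- which(raw$chrom == "chr2")[100:149]
  expect_equal(raw$log2_ratio[sel], rep(0.6, 50), tolerance = 1e-12)
  # with library-size normalization the inside-outside contrast is preserved
  norm <- log_ratio(p, m)
  out <- setdiff(which(norm$chrom == "chr2"), sel)
  expect_equal(mean(norm$log2_ratio[sel]) - mean(norm$log2_ratio[out]), 0.6,
               tolerance = 1e-12)
})

test_that("CBS returns one segment for constant input", {
  segs <- cbs_segment(rep(0.3, 40), n_perm = 100, seed = 1)
  expect_identical(nrow(segs), 1L)
  expect_identical(segs$start_bin, 1L)
  expect_identical(segs$end_bin, 40L)
  expect_equal(segs$smoothed_value, 0.3)
})

test_that("CBS finds a clean step within one bin", {
  set.seed(42)
  x <- c(rnorm(30, 0, 0.05), rnorm(30, 1, 0.05))
  segs <- cbs_segment(x, n_perm = 500, seed = 8)
  expect_identical(nrow(segs), 2L)
  expect_true(abs(segs$end_bin[1] - 30L) <= 1L)
  expect_equal(segs$smoothed_value, c(0, 1), tolerance = 0.1)
})

test_that("the split finder agrees with a brute-force arc search", {
  set.seed(99)
  agree <- 0L
  n_trials <- 30L
  for (t in seq_len(n_trials)) {
    n <- sample(10:50, 1)
    x <- rnorm(n) + rep(c(0, sample(c(-1, 1), 1)), c(n %/% 2, n - n %/% 2))
    got <- cbs_max_arc(x, 3L)
    want <- brute_max_arc(x, 3L)
    if (got$i == want$i && got$j == want$j) agree <- agree + 1L
  }
  expect_gte(agree, ceiling(0.95 * n_trials))
})

test_that("masked bins belong to no segment and bounds map back", {
  x <- c(rnorm(20, 0, 0.01), NA, NA, rnorm(20, 2, 0.01))
  segs <- cbs_segment(x, n_perm = 200, seed = 3)
  expect_identical(nrow(segs), 2L)
  expect_identical(segs$start_bin, c(1L, 23L))
  expect_identical(segs$end_bin, c(20L, 42L))
  expect_identical(segs$n_bins, c(20L, 20L))
  expect_warning(res <- cbs_segment(rep(NA_real_, 10), n_perm = 100),
                 "masked")
  expect_identical(nrow(res), 0L)
})

test_that("zero level is the bin-count-weighted mode", {
  one <- data.frame(smoothed_value = 0.37, n_bins = 10L)
  expect_equal(zero_level(one), 0.37)
  two <- data.frame(smoothed_value = c(0.02, 0.61), n_bins = c(200L, 50L))
  expect_equal(zero_level(two), 0.02)
  # translation equivariance
  shifted <- two
  shifted$smoothed_value <- shifted$smoothed_value + 0.83
  expect_equal(zero_level(shifted), 0.02 + 0.83)
  # tie: value nearest zero wins, with a warning
  tie <- data.frame(smoothed_value = c(-0.4, 0.1), n_bins = c(10L, 10L))
  expect_warning(z <- zero_level(tie), "tie")
  expect_equal(z, 0.1)
})

test_that("state calling uses strict thresholds around the zero level", {
  zero <- 0.02
  segs <- data.frame(smoothed_value = zero + c(0, 0.15, 0.16, 2, 2.01,
                                               -0.15, -0.16, -2, -2.01),
                     n_bins = 1L)
  st <- call_states(segs, zero)$state
  expect_identical(st, c("neutral", "neutral", "gain", "gain",
                         "amplification", "neutral", "deletion", "deletion",
                         "homozygous_deletion"))
  # translation invariance away from the exact thresholds: shifting data
  # and zero together changes no label
  generic <- data.frame(smoothed_value = zero + c(0, 0.14, 0.16, 1.9, 2.01,
                                                  -0.14, -0.16, -1.9, -2.01),
                        n_bins = 1L)
  st_g <- call_states(generic, zero)$state
  shifted <- generic
  shifted$smoothed_value <- shifted$smoothed_value + 1.7
  expect_identical(call_states(shifted, zero + 1.7)$state, st_g)
})

test_that("recurrent regions accumulate across patients on a shared grid", {
  seg <- function(state_mid) data.frame(
    chrom = "chr1", start_bin = c(1L, 31L, 61L), end_bin = c(30L, 60L, 100L),
    state = c("neutral", state_mid, "neutral"), stringsAsFactors = FALSE)
  tabs <- list(P1 = seg("gain"), P2 = seg("gain"), P3 = seg("amplification"))
  rec <- recurrent_regions(tabs, min_patients = 3, state = "gain")
  expect_identical(rec$start_bin, 31L)
  expect_identical(rec$end_bin, 60L)
  expect_identical(rec$max_patients, 3L)
  # k above cohort size: empty report
  expect_identical(nrow(recurrent_regions(tabs, min_patients = 4)), 0L)
  # fewer than two patients is an error
  expect_error(recurrent_regions(tabs[1], 1), "at least 2")
  # inconsistent grids are an error
  bad <- seg("gain"); bad$end_bin[3] <- 90L
  expect_error(recurrent_regions(list(P1 = seg("gain"), P2 = bad), 2),
               "grid")
})

test_that("cna_pipeline recovers a planted gain with correct state", {
  cfg <- small_cohort_config(
    seed = 17, n_patients = 1, bin_noise_sd = 0.1,
    planted_segments = data.frame(chrom = "chr1", start_bin = 46L,
                                  end_bin = 95L, log2_ratio = 0.6))
  co <- generate_cohort(cfg)
  res <- cna_pipeline(co$coverage$P1_primary, co$coverage$P1_met,
                      n_perm = 500, seed = 4)
  gains <- res$segments[res$segments$state %in% c("gain", "amplification") &
                          res$segments$chrom == "chr1", ]
  expect_identical(nrow(gains), 1L)
  expect_true(abs(gains$start_bin - 46L) <= 2L)
  expect_true(abs(gains$end_bin - 95L) <= 2L)
  expect_equal(gains$smoothed_value - res$zero, 0.6, tolerance = 0.1)
})
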