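test_that("identical seeds reproduce bit-identical cohorts", {
  a <- demo_cohort(seed = 55)
  b <- demo_cohort(seed = 55)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  a2 <- simulate_snp_allele_counts(a, depth = 50)
  b2 <- simulate_snp_allele_counts(b, depth = 50)
  expect_identical(a2$snp_counts, b2$snp_counts)
})

test_that("with no events and no count noise the generating mean is recovered", {
  design <- make_capture_design(1, 100, 200, seed = 3)
  co <- simulate_counts(design, 5, mean_depth = 50, dispersion = 0,
                        sample_depth_cv = 0, capture_sigma = 0, seed = 4,
                        sexes = rep("F", 5))
  m <- as.matrix(co$counts[, paste0("S", 1:5)])
  # Poisson with mean 50 per window: sample mean within 3 SE
  for (s in 1:5) {
    se <- sqrt(50 / nrow(m))
    expect_lt(abs(mean(m[, s]) - 50), 3 * se)
  }
})

test_that("window count variance matches the stated dispersion at scale", {
  design <- make_capture_design(1, 5000, 200, seed = 8)
  co <- simulate_counts(design, 1, mean_depth = 60, dispersion = 0.05,
                        sample_depth_cv = 0, capture_sigma = 0, seed = 9,
                        sexes = "F")
  x <- co$counts$S1
  expect_gt(length(x), 9999)
  expect_lt(abs(mean(x) - 60) / 60, 0.02)
  v_expected <- 60 * (1 + 0.05 * 60)
  expect_lt(abs(var(x) - v_expected) / v_expected, 0.10)
})

test_that("a whole-chromosome CN=3 event raises that chromosome ~1.5x", {
  design <- make_capture_design(5, 100, 200, seed = 2)
  ev <- truth_event("S1", "chr2", copy_number = 3, class = "aneuploidy")
  ratios <- vapply(1:20, function(s) {
    co <- simulate_counts(design, 20, mean_depth = 40, events = ev,
                          sample_depth_cv = 0, seed = 1000 + s,
                          sexes = rep("F", 20))
    m <- as.matrix(co$counts[, paste0("S", 1:20)])
    on2 <- co$counts$chrom == "chr2"
    mean(m[on2, 1]) / mean(m[on2, -1])
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1.5), 0.03)
})

test_that("male chrY mosaic loss at f = 0.5 halves chrY coverage", {
  design <- make_capture_design(4, 200, 200, seed = 6, chry_frac = 0.5)
  ev <- truth_event("S1", "chrY", copy_number = 0, mosaic_fraction = 0.5,
                    class = "aneuploidy")
  co <- simulate_counts(design, 6, mean_depth = 80, events = ev,
                        sample_depth_cv = 0, seed = 21,
                        sexes = rep("M", 6))
  m <- as.matrix(co$counts[, paste0("S", 1:6)])
  on_y <- co$counts$chrom == "chrY"
  obs <- mean(m[on_y, 1]) / mean(m[on_y, -1])
  expect_lt(abs(obs - 0.5), 0.05)
})

test_that("female samples have no chrY reads and half-depth male chrX", {
  design <- make_capture_design(4, 80, 200, seed = 10)
  co <- simulate_counts(design, 6, mean_depth = 100, dispersion = 0,
                        sample_depth_cv = 0, capture_sigma = 0, seed = 11,
                        sexes = c(rep("M", 3), rep("F", 3)))
  m <- as.matrix(co$counts[, paste0("S", 1:6)])
  on_y <- co$counts$chrom == "chrY"
  on_x <- co$counts$chrom == "chrX"
  expect_true(all(m[on_y, 4:6] == 0))
  expect_gt(mean(m[on_y, 1:3]), 50)
  expect_lt(abs(mean(m[on_x, 1:3]) / mean(m[on_x, 4:6]) - 0.5), 0.05)
})

test_that("polymorphic events hit a subset of samples, making CN divergent", {
  design <- make_capture_design(2, 60, 200, seed = 13)
  ev <- truth_event(NA, "chr1", 20000, 60000, copy_number = 1,
                    class = "polymorphic_cnv")
  co <- simulate_counts(design, 30, mean_depth = 60, events = ev, seed = 14,
                        sexes = rep("F", 30), polymorphic_freq = 0.3)
  carriers <- unique(co$truth$sample)
  expect_gt(length(carriers), 2)
  expect_lt(length(carriers), 30)
  expect_true(all(co$truth$class == "polymorphic_cnv"))
})

test_that("snp allele fractions track constitutional copy number", {
  design <- make_capture_design(3, 80, 300, seed = 16)
  ev <- dplyr::bind_rows(
    truth_event("S1", "chr1", 5000, 200000, copy_number = 3),
    truth_event("S1", "chr2", 5000, 200000, copy_number = 1)
  )
  co <- simulate_counts(design, 4, mean_depth = 60, events = ev, seed = 17,
                        sexes = rep("F", 4))
  co <- simulate_snp_allele_counts(co, het_snps_per_kb = 5, depth = 100,
                                   seed = 18)
  snp <- co$snp_counts
  frac <- snp$alt_count / (snp$ref_count + snp$alt_count)
  in_dup <- snp$sample == "S1" & snp$chrom == "chr1" &
    snp$pos - 1 >= 5000 & snp$pos - 1 < 200000
  in_del <- snp$sample == "S1" & snp$chrom == "chr2" &
    snp$pos - 1 >= 5000 & snp$pos - 1 < 200000
  diploid <- snp$sample == "S2"

  expect_lt(abs(mean(frac[diploid]) - 0.5), 0.02)
  # duplication: modes at the 1/3 and 2/3 allele dosages
  lo <- frac[in_dup][frac[in_dup] < 0.5]
  hi <- frac[in_dup][frac[in_dup] >= 0.5]
  expect_lt(abs(mean(lo) - 1 / 3), 0.03)
  expect_lt(abs(mean(hi) - 2 / 3), 0.03)
  expect_gt(mean(abs(frac[in_dup] - 0.5) > 0.1), 0.85)
  # het deletion: hemizygous, < 5% of sites in the mid band at depth 100
  expect_lt(mean(frac[in_del] > 0.2 & frac[in_del] < 0.8), 0.05)
})

test_that("array call sets apply size threshold, jitter and exclusions", {
  truth <- dplyr::bind_rows(
    truth_event("S1", "chr1", 100000, 1100000, copy_number = 1),
    truth_event("S2", "chr1", 5000, 10000, copy_number = 3),      # 5 kb
    truth_event("S3", "chr2", copy_number = 3, class = "aneuploidy")
  )
  truth$start[3] <- 0; truth$end[3] <- 2e6  # expanded form
  gold0 <- derive_array_callset(truth, breakpoint_jitter_bp = 0,
                                min_size_bp = 10000, seed = 1)
  expect_equal(nrow(gold0), 1)
  expect_equal(gold0$start, 100000)
  expect_equal(gold0$end, 1100000)

  gold5 <- derive_array_callset(truth, breakpoint_jitter_bp = 5000,
                                min_size_bp = 10000, seed = 2)
  j <- jaccard_similarity(gold5[1, c("chrom", "start", "end")],
                          truth[1, c("chrom", "start", "end")])
  expect_gt(j, 0.9)  # 5 kb jitter on a 1 Mb event
})

test_that("event bookkeeping is conserved between truth and array set", {
  co <- demo_cohort(seed = 77)
  gold <- derive_array_callset(co$truth, breakpoint_jitter_bp = 1000,
                               min_size_bp = 10000, seed = 3)
  n_aneu <- sum(co$truth$class == "aneuploidy")
  n_small <- sum(co$truth$class != "aneuploidy" &
                   co$truth$end - co$truth$start < 10000)
  expect_equal(nrow(co$truth), nrow(gold) + n_aneu + n_small)
})

test_that("events on unknown chromosomes or samples are rejected", {
  design <- make_capture_design(2, 20, 200, seed = 1)
  ev <- truth_event("S1", "chr9", 0, 1000, copy_number = 1)
  expect_error(simulate_counts(design, 3, events = ev, seed = 1,
                               sexes = rep("F", 3)), "chromosome")
  ev2 <- truth_event("S99", "chr1", 0, 1000, copy_number = 1)
  expect_error(simulate_counts(design, 3, events = ev2, seed = 1,
                               sexes = rep("F", 3)), "sample")
})
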