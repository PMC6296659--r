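test_that("state_fraction performs the dosage odds arithmetic", {
  expect_equal(state_fraction(0.5, 2), 0.5)
  expect_equal(state_fraction(0.5, 1), 1 / 3)
  expect_equal(state_fraction(0.5, 3), 3 / 5)
  expect_equal(state_fraction(0.5, 0), 1e-4)  # floored
  expect_equal(state_fraction(0.2, 2), 0.2)
})

test_that("beta-binomial density degenerates to binomial and normalizes", {
  y <- 0:20
  expect_equal(dbetabinom_log(y, 20, 0.3, 0), dbinom(y, 20, 0.3, log = TRUE))
  for (theta in c(0.001, 0.01, 0.2)) {
    expect_equal(sum(exp(dbetabinom_log(0:15, 15, 0.4, theta))), 1,
                 tolerance = 1e-10)
  }
  # overdispersion fattens the tails relative to binomial
  expect_gt(dbetabinom_log(0, 50, 0.5, 0.1), dbinom(0, 50, 0.5, log = TRUE))
})

test_that("emission fit gives phi = 1/2 for identical test and reference", {
  y <- c(10, 40, 25, 60, 31)
  p <- fit_emission_params(y, y)
  expect_true(all(abs(p$phi - 0.5) < 1e-12))
  expect_error(fit_emission_params(y, rep(0, 5)), "zero")
})

test_that("theta is near zero for binomial data and recovers a true value", {
  set.seed(31)
  n <- rpois(10000, 200) + 1
  phi <- 0.5
  y <- rbinom(length(n), n, phi)
  p <- fit_emission_params(y, n - y)
  expect_lt(p$theta, 0.001)

  # beta-binomial with known theta = 0.01
  theta_true <- 0.01
  a <- phi * (1 - theta_true) / theta_true
  b <- (1 - phi) * (1 - theta_true) / theta_true
  pr <- rbeta(length(n), a, b)
  y2 <- rbinom(length(n), n, pr)
  p2 <- fit_emission_params(y2, n - y2)
  expect_lt(abs(p2$theta - theta_true) / theta_true, 0.2)
})

test_that("viterbi equals exhaustive path enumeration on small instances", {
  set.seed(41)
  log_trans <- wescnv:::hmm_log_trans(1e-3, 10)
  log_init <- log(c(5e-4, 0.999, 5e-4))
  for (rep in 1:60) {
    w <- sample(2:10, 1)
    n <- rpois(w, 80) + 1
    truth_state <- sample(1:3, 1)
    f <- state_fraction(0.5, c(1, 2, 3))
    y <- rbinom(w, n, f[truth_state])
    log_emis <- vapply(1:3, function(k) dbinom(y, n, f[k], log = TRUE),
                       numeric(w))
    got <- wescnv:::viterbi_decode(log_emis, log_trans, log_init)
    want <- enumerate_best_path(log_emis, log_trans, log_init)
    expect_equal(got, unname(want))
  }
})

test_that("an exactly diploid profile yields no calls", {
  design <- make_capture_design(2, 50, 200, seed = 1)
  co <- simulate_counts(design, 6, mean_depth = 100, dispersion = 0,
                        sample_depth_cv = 0, capture_sigma = 0, seed = 2,
                        sexes = rep("F", 6))
  # replace counts with a noise-free profile shared by every sample
  profile <- 80L + (seq_len(nrow(co$counts)) %% 41L)
  co$counts[paste0("S", 1:6)] <- profile
  ref <- select_reference(co$counts, "S1")
  calls <- call_cnvs(co$counts, "S1", ref)
  expect_equal(nrow(calls), 0)
})

test_that("no-event cohorts yield no calls across seeds", {
  for (seed in c(3, 17, 29)) {
    co <- null_cohort(seed = seed, n_samples = 8)
    calls <- call_cohort(co$counts)
    expect_equal(nrow(calls), 0)
  }
})

test_that("a simulated het deletion is called with correct state and bounds", {
  design <- make_capture_design(2, 120, 200, seed = 51)
  hits <- 0
  n_seeds <- 20
  for (seed in seq_len(n_seeds)) {
    ev <- truth_event("S1", "chr1", 100000, 140000, copy_number = 1)
    co <- simulate_counts(design, 21, mean_depth = 100, events = ev,
                          seed = 600 + seed, sexes = rep("F", 21))
    ref <- select_reference(co$counts, "S1", max_members = 20)
    calls <- call_cnvs(co$counts, "S1", ref)
    del <- calls[calls$cn == 1 & calls$chrom == "chr1", ]
    if (nrow(del) > 0) {
      ro <- max(reciprocal_overlap(
        del[, c("chrom", "start", "end")],
        tibble::tibble(chrom = "chr1", start = 100000, end = 140000)))
      if (ro >= 0.5) hits <- hits + 1
    }
  }
  expect_gte(hits, n_seeds - 1)
})

test_that("emitted calls always carry positive Bayes factors", {
  co <- demo_cohort(seed = 91)
  calls <- call_cohort(co$counts)
  expect_gt(nrow(calls), 0)
  expect_true(all(calls$bayes_factor > 0))
  expect_true(all(calls$n_windows >= 1))
})

test_that("doubling all counts preserves boundaries and increases BF", {
  design <- make_capture_design(1, 100, 200, seed = 61)
  ev <- truth_event("S1", "chr1", 50000, 90000, copy_number = 1)
  co <- simulate_counts(design, 10, mean_depth = 60, events = ev, seed = 62,
                        sexes = rep("F", 10))
  ref <- select_reference(co$counts, "S1")
  calls1 <- call_cnvs(co$counts, "S1", ref)

  doubled <- co$counts
  doubled[paste0("S", 1:10)] <- doubled[paste0("S", 1:10)] * 2L
  ref2 <- select_reference(doubled, "S1")
  calls2 <- call_cnvs(doubled, "S1", ref2)

  expect_equal(nrow(calls2), nrow(calls1))
  expect_equal(calls2$start, calls1$start)
  expect_equal(calls2$end, calls1$end)
  expect_true(all(calls2$bayes_factor > calls1$bayes_factor))
})

test_that("reference selection ranks by correlation with deterministic ties", {
  design <- make_capture_design(1, 80, 200, seed = 71)
  co <- simulate_counts(design, 2, mean_depth = 80, seed = 72,
                        sexes = rep("F", 2))
  # clone S1 into 5 identical samples: all correlations 1, id order wins
  counts <- co$counts
  for (s in paste0("S", 3:6)) counts[[s]] <- counts$S2
  ref <- select_reference(counts, "S1", max_members = 3)
  expect_equal(ref$members[1], "S2")
  expect_lte(length(ref$members), 3)
  ref1 <- select_reference(counts, "S1", max_members = 1)
  expect_equal(length(ref1$members), 1)

  expect_error(select_reference(counts[, 1:5], "S1"), "2 samples")
})

test_that("a correlated sample is preferred over an uncorrelated one", {
  design <- make_capture_design(1, 200, 200, seed = 81)
  co <- simulate_counts(design, 2, mean_depth = 100, capture_sigma = 0.6,
                        seed = 82, sexes = rep("F", 2))
  counts <- co$counts
  # S3: same capture profile as S1/S2 (correlated); S4: profile shuffled
  set.seed(83)
  counts$S3 <- rpois(nrow(counts), pmax(counts$S1, 1))
  counts$S4 <- sample(counts$S3)
  ref <- select_reference(counts, "S1")
  expect_true(ref$members[1] %in% c("S2", "S3"))
  scores <- ref$scores
  expect_gt(scores$correlation[scores$sample == "S3"],
            scores$correlation[scores$sample == "S4"])
})

test_that("genotype ratio maps depth to integer CN labels", {
  design <- make_capture_design(1, 200, 200, seed = 85)
  co <- simulate_counts(design, 6, mean_depth = 100, dispersion = 0,
                        sample_depth_cv = 0, capture_sigma = 0, seed = 86,
                        sexes = rep("F", 6))
  counts <- co$counts
  profile <- 80L + (seq_len(nrow(counts)) %% 41L)
  counts[paste0("S", 1:6)] <- profile
  half <- counts
  half$S1[1:20] <- as.integer(round(profile[1:20] / 2))
  ref <- select_reference(half, "S1", max_members = 5)
  call <- tibble::tibble(chrom = "chr1", start = counts$start[1],
                         end = counts$end[20])
  gr <- genotype_ratio(call, half, "S1", ref)
  expect_lt(abs(gr$observed_ratio - 0.5), 0.03)
  expect_equal(gr$cn_label, 1L)

  onehalf <- counts
  onehalf$S1[1:20] <- as.integer(round(profile[1:20] * 1.5))
  ref2 <- select_reference(onehalf, "S1", max_members = 5)
  gr2 <- genotype_ratio(call, onehalf, "S1", ref2)
  expect_equal(gr2$cn_label, 3L)
})

test_that("mismatched window sets are rejected", {
  co <- null_cohort(seed = 44, n_samples = 5)
  ref <- select_reference(co$counts, "S1")
  expect_error(call_cnvs(co$counts[-1, ], "S1", ref), "window")
  expect_error(call_cnvs(co$counts, "S2", ref), "another sample")
})
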