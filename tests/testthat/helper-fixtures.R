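# Shared fixtures, built in code at test time.

# Small mixed-sex cohort with one focal deletion, one focal duplication
# and one trisomy, at depths where every event is clearly detectable.
demo_cohort <- function(seed = 101, n_samples = 12, mean_depth = 80) {
  design <- make_capture_design(20, 40, 200, seed = seed,
                                mean_gap_bp = 3000)
  events <- dplyr::bind_rows(
    truth_event("S1", "chr3", 10000, 110000, copy_number = 1),
    truth_event("S2", "chr5", 20000, 100000, copy_number = 3),
    truth_event("S4", "chr7", copy_number = 3, class = "aneuploidy")
  )
  simulate_counts(design, n_samples, mean_depth = mean_depth,
                  events = events, seed = seed + 1,
                  sexes = rep(c("M", "F"), length.out = n_samples))
}

# Event-free cohort for null behavior checks.
null_cohort <- function(seed = 7, n_samples = 10, n_chrom = 6,
                        targets = 40, mean_depth = 60, dispersion = 0.02) {
  design <- make_capture_design(n_chrom, targets, 200, seed = seed)
  simulate_counts(design, n_samples, mean_depth = mean_depth,
                  dispersion = dispersion, seed = seed + 1,
                  sexes = rep("F", n_samples))
}

# The pilot-style validation fixture: eight samples, four megabase-scale
# focal events at the sizes reported for the validation cases
# (~1.1, 1.4, 5.7, 1.4 Mb) plus one whole-chromosome trisomy, and three
# event-free negatives.
pilot_cohort <- function(seed) {
  design <- make_capture_design(7, 300, 200, seed = 1,
                                mean_gap_bp = 26000)
  events <- dplyr::bind_rows(
    truth_event("S1", "chr1", 1.0e6, 2.1e6, copy_number = 1),
    truth_event("S2", "chr2", 2.0e6, 3.4e6, copy_number = 3),
    truth_event("S3", "chr3", 1.5e6, 7.2e6, copy_number = 1),
    truth_event("S4", "chr4", 3.0e6, 4.4e6, copy_number = 3),
    truth_event("S5", "chr5", copy_number = 3, class = "aneuploidy")
  )
  simulate_counts(design, 8, mean_depth = 62, events = events,
                  seed = seed, sexes = rep(c("M", "F"), 4))
}

# Brute-force Viterbi oracle: enumerate all 3^W state paths and return
# the highest-scoring one. Independent of the decoder under test.
enumerate_best_path <- function(log_emis, log_trans, log_init) {
  w <- nrow(log_emis)
  paths <- as.matrix(expand.grid(rep(list(1:3), w)))
  score <- log_init[paths[, 1]] + log_emis[1, ][paths[, 1]]
  if (w > 1) {
    for (t in 2:w) {
      score <- score + log_trans[cbind(paths[, t - 1], paths[, t])] +
        log_emis[t, ][paths[, t]]
    }
  }
  paths[which.max(score), ]
}

# Brute-force Jaccard on explicit basepair sets (0-based half-open).
jaccard_bruteforce <- function(s1, e1, s2, e2) {
  a <- seq(s1, e1 - 1)
  b <- seq(s2, e2 - 1)
  length(intersect(a, b)) / length(union(a, b))
}
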