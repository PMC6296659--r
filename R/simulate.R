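#' Construct a table of truth events for simulation
#'
#' A truth event places a non-diploid segment in one sample (or, for
#' `polymorphic_cnv`, in a random subset of samples chosen at simulation
#' time). Copy number 2 is the diploid reference and is not a valid event
#' state; `mosaic_fraction` is the fraction of cells carrying the event
#' (1 = constitutional). `aneuploidy` events must span a whole chromosome,
#' which is expressed by giving the chromosome and leaving `start`/`end`
#' as `NA` (they are expanded to the full chromosome when simulated).
#'
#' @param sample Sample id (e.g. `"S1"`), or `NA` for `polymorphic_cnv`.
#' @param chrom Chromosome label matching the capture design.
#' @param start,end 0-based half-open span; `NA` for whole-chromosome
#'   aneuploidy.
#' @param copy_number Integer copy number `>= 0`, not 2.
#' @param mosaic_fraction In `(0, 1]`.
#' @param class One of `"focal_cnv"`, `"aneuploidy"`, `"polymorphic_cnv"`.
#' @return A one-row tibble; rows from repeated calls bind with
#'   [dplyr::bind_rows()].
#' @export
truth_event <- function(sample, chrom, start = NA_real_, end = NA_real_,
                        copy_number, mosaic_fraction = 1,
                        class = "focal_cnv") {
  if (!class %in% c("focal_cnv", "aneuploidy", "polymorphic_cnv")) {
    abort("unknown event class")
  }
  if (copy_number == 2 || copy_number < 0 || copy_number != floor(copy_number)) {
    abort("`copy_number` must be a non-negative integer other than 2")
  }
  if (mosaic_fraction <= 0 || mosaic_fraction > 1) {
    abort("`mosaic_fraction` must be in (0, 1]")
  }
  if (class == "aneuploidy" && !(is.na(start) && is.na(end))) {
    abort("aneuploidy events span the whole chromosome; leave start/end NA")
  }
  tibble::tibble(sample = as.character(sample), chrom = chrom,
                 start = as.numeric(start), end = as.numeric(end),
                 copy_number = as.integer(copy_number),
                 mosaic_fraction = as.numeric(mosaic_fraction),
                 class = class)
}

#' Simulate window read counts for a cohort
#'
#' Draws overdispersed read counts per 100 bp window per sample under the
#' generative model the read-depth caller assumes: the count for sample
#' \eqn{s} in window \eqn{w} has mean
#' \eqn{d_s \mu_w D \cdot \mathrm{CN}_{s,w} / P_{s,c}} where \eqn{D} is
#' `mean_depth`, \eqn{d_s} a per-sample depth factor with coefficient of
#' variation `sample_depth_cv`, \eqn{\mu_w} a log-normal per-window
#' capture-efficiency factor shared across samples, and
#' \eqn{P_{s,c}} the sample's baseline ploidy on the window's chromosome
#' (2 on autosomes; chrX 2 in females / 1 in males; chrY 1 in males /
#' 0 in females). Counts are negative-binomial with variance
#' `mean * (1 + dispersion * mean)`; `dispersion = 0` gives Poisson.
#'
#' Mosaic events at fraction \eqn{f} have effective copy number
#' \eqn{P + f(\mathrm{CN} - P)}, so a male chrY loss at \eqn{f = 0.5}
#' yields chrY coverage at 50% of the male expectation.
#' `polymorphic_cnv` events are assigned independently to a random subset
#' of samples (each carrying with probability `polymorphic_freq`), making
#' the region copy-number divergent across the cohort.
#'
#' @param design A `capture_design` from [make_capture_design()].
#' @param n_samples Number of samples.
#' @param mean_depth Mean reads per window in a diploid region.
#' @param dispersion Overdispersion `>= 0` of the count noise.
#' @param events Tibble of truth events (see [truth_event()]), or `NULL`.
#' @param sample_depth_cv Coefficient of variation of per-sample depth.
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @param sexes Character vector `"M"`/`"F"` per sample; default draws
#'   each sex with probability 1/2.
#' @param window_bp Window width passed to [bin_capture_regions()].
#' @param capture_sigma Log-scale SD of the per-window efficiency
#'   \eqn{\mu_w}.
#' @param polymorphic_freq Carrier probability for `polymorphic_cnv`
#'   events.
#' @return A `wescnv_cohort` list: `design`, `counts` (wide tibble:
#'   `chrom`, `start`, `end`, `window_id`, then one column per sample),
#'   `truth` (expanded per-carrier events with realized coordinates),
#'   `snp_counts` (`NULL` until [simulate_snp_allele_counts()]), `sexes`,
#'   `seed`.
#' @export
simulate_counts <- function(design, n_samples, mean_depth = 62,
                            dispersion = 0.02, events = NULL,
                            sample_depth_cv = 0.1, seed = 1,
                            sexes = NULL, window_bp = 100,
                            capture_sigma = 0.4, polymorphic_freq = 0.3) {
  if (!is_count(n_samples)) abort("`n_samples` must be a positive integer")
  if (mean_depth <= 0) abort("`mean_depth` must be > 0")
  if (dispersion < 0) abort("`dispersion` must be >= 0")
  windows <- bin_capture_regions(design, window_bp = window_bp)
  sample_ids <- paste0("S", seq_len(n_samples))
  chrom_lengths <- attr(design, "chrom_lengths") %||%
    (design |> dplyr::group_by(.data$chrom) |>
       dplyr::summarise(len = max(.data$end)) |> tibble::deframe())

  if (!is.null(events) && nrow(events) > 0) {
    assert_columns(events, c("sample", "chrom", "start", "end",
                             "copy_number", "mosaic_fraction", "class"),
                   "events")
    bad <- setdiff(events$chrom, unique(design$chrom))
    if (length(bad) > 0) {
      abort(paste0("event chromosome(s) not in design: ",
                   paste(bad, collapse = ", ")))
    }
    known <- !is.na(events$sample) & !events$sample %in% sample_ids &
      events$class != "polymorphic_cnv"
    if (any(known)) abort("event sample id not in cohort")
  }

  with_seed(seed, {
    if (is.null(sexes)) {
      sexes <- sample(c("M", "F"), n_samples, replace = TRUE)
    }
    if (length(sexes) != n_samples || !all(sexes %in% c("M", "F"))) {
      abort("`sexes` must be 'M'/'F' of length n_samples")
    }
    names(sexes) <- sample_ids

    d_s <- if (sample_depth_cv > 0) {
      sdlog <- sqrt(log(1 + sample_depth_cv^2))
      rlnorm(n_samples, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else rep(1, n_samples)
    mu_w <- if (capture_sigma > 0) {
      rlnorm(nrow(windows), meanlog = -capture_sigma^2 / 2,
             sdlog = capture_sigma)
    } else rep(1, nrow(windows))

    # baseline ploidy per window x sample
    ploidy <- matrix(2, nrow(windows), n_samples)
    is_x <- windows$chrom == "chrX"
    is_y <- windows$chrom == "chrY"
    for (s in seq_len(n_samples)) {
      if (sexes[s] == "M") ploidy[is_x, s] <- 1 else ploidy[is_x, s] <- 2
      ploidy[is_y, s] <- if (sexes[s] == "M") 1 else 0
    }

    truth <- expand_events(events, sample_ids, chrom_lengths,
                           polymorphic_freq)

    # effective CN matrix starts at baseline ploidy
    eff <- ploidy
    if (nrow(truth) > 0) {
      for (i in seq_len(nrow(truth))) {
        s <- match(truth$sample[i], sample_ids)
        hit <- windows$chrom == truth$chrom[i] &
          windows$end > truth$start[i] & windows$start < truth$end[i]
        p <- ploidy[hit, s]
        f <- truth$mosaic_fraction[i]
        eff[hit, s] <- p + f * (truth$copy_number[i] - p)
      }
    }

    # dosage denominator: autosomes and chrX are expressed relative to
    # the diploid reference (CN/2); chrY relative to the single male copy
    denom <- ifelse(is_y, 1, 2)
    mu <- sweep(mu_w * mean_depth * (eff / denom), 2, d_s, `*`)
    counts <- if (dispersion == 0) {
      matrix(rpois(length(mu), lambda = mu), nrow(windows), n_samples)
    } else {
      matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
             nrow(windows), n_samples)
    }
    colnames(counts) <- sample_ids
    counts_tbl <- dplyr::bind_cols(
      windows[, c("chrom", "start", "end", "window_id")],
      tibble::as_tibble(counts)
    )
    structure(
      list(design = design, windows = windows, counts = counts_tbl,
           truth = truth, snp_counts = NULL, sexes = sexes, seed = seed),
      class = "wescnv_cohort"
    )
  })
}

# Expand whole-chromosome aneuploidies to full spans and polymorphic
# events to per-carrier rows.
expand_events <- function(events, sample_ids, chrom_lengths, freq) {
  empty <- tibble::tibble(sample = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          copy_number = integer(),
                          mosaic_fraction = numeric(), class = character())
  if (is.null(events) || nrow(events) == 0) return(empty)
  rows <- purrr::map(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    if (ev$class == "aneuploidy" || is.na(ev$start)) {
      ev$start <- 0
      ev$end <- as.numeric(chrom_lengths[[ev$chrom]])
    }
    if (ev$class == "polymorphic_cnv") {
      carriers <- sample_ids[runif(length(sample_ids)) < freq]
      if (length(carriers) == 0) return(empty)
      out <- ev[rep(1L, length(carriers)), ]
      out$sample <- carriers
      return(out)
    }
    ev
  })
  dplyr::bind_rows(rows)
}

#' @export
print.wescnv_cohort <- function(x, ...) {
  cat("<wescnv_cohort> ", ncol(x$counts) - 4L, " samples, ",
      nrow(x$counts), " windows, ", nrow(x$truth), " truth events",
      if (!is.null(x$snp_counts)) paste0(", ", nrow(x$snp_counts), " SNP rows"),
      " (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Summarise a simulated cohort
#'
#' @param x A `wescnv_cohort`.
#' @param ... Unused.
#' @return One-row tibble with sample/window/event totals and the seed.
#' @export
glance.wescnv_cohort <- function(x, ...) {
  tibble::tibble(
    n_samples = ncol(x$counts) - 4L,
    n_windows = nrow(x$counts),
    n_truth_events = nrow(x$truth),
    n_snp_rows = if (is.null(x$snp_counts)) 0L else nrow(x$snp_counts),
    seed = x$seed
  )
}

#' Simulate het-SNP allele counts over a cohort
#'
#' Scatters heterozygous SNP sites across capture regions at
#' `het_snps_per_kb` and draws reference/alternate read counts per sample
#' by binomial sampling at a Poisson site depth. The alternate-read
#' fraction tracks allele dosage in constitutional events: ~1/2 in diploid
#' regions, 1/3 or 2/3 (random phase) in CN 3 duplications, near 0 or 1 in
#' CN 1 deletions (hemizygous), and no reads in CN 0. Regions under mosaic
#' (f < 1) events are treated as diploid for allele fractions: depth-only
#' mosaics are the target of the ploidy module, not the VAF annotation.
#'
#' @param cohort A `wescnv_cohort`.
#' @param het_snps_per_kb Mean het sites per kb of capture target.
#' @param depth Mean site depth (reads).
#' @param seed Integer seed (defaults to a stream derived from the
#'   cohort's seed).
#' @param error_rate Sequencing error floor for hemizygous fractions.
#' @return The cohort with `snp_counts` filled: `sample`, `chrom`, `pos`
#'   (1-based), `ref_count`, `alt_count`.
#' @export
simulate_snp_allele_counts <- function(cohort, het_snps_per_kb = 0.5,
                                       depth = 62, seed = NULL,
                                       error_rate = 0.02) {
  stopifnot(inherits(cohort, "wescnv_cohort"))
  if (het_snps_per_kb <= 0) abort("`het_snps_per_kb` must be > 0")
  if (depth <= 0) abort("`depth` must be > 0")
  seed <- seed %||% derive_seed(cohort$seed, 11L)
  design <- cohort$design
  sample_ids <- setdiff(names(cohort$counts),
                        c("chrom", "start", "end", "window_id"))
  with_seed(seed, {
    n_sites <- rpois(nrow(design),
                     (design$end - design$start) / 1000 * het_snps_per_kb)
    sites <- purrr::map(which(n_sites > 0), function(i) {
      pos0 <- sort(sample(design$start[i]:(design$end[i] - 1L), n_sites[i]))
      tibble::tibble(chrom = design$chrom[i], pos = pos0 + 1L)  # 1-based
    }) |> dplyr::bind_rows()
    if (nrow(sites) == 0) {
      cohort$snp_counts <- tibble::tibble(
        sample = character(), chrom = character(), pos = integer(),
        ref_count = integer(), alt_count = integer())
      return(cohort)
    }
    const <- cohort$truth |>
      dplyr::filter(.data$mosaic_fraction == 1)
    per_sample <- purrr::map(sample_ids, function(sid) {
      cn <- rep(2L, nrow(sites))
      ev <- const[const$sample == sid, ]
      if (nrow(ev) > 0) {
        for (j in seq_len(nrow(ev))) {
          hit <- sites$chrom == ev$chrom[j] & sites$pos - 1L >= ev$start[j] &
            sites$pos - 1L < ev$end[j]
          cn[hit] <- ev$copy_number[j]
        }
      }
      n <- rpois(nrow(sites), depth)
      p <- dplyr::case_when(
        cn == 2L ~ 0.5,
        cn == 3L ~ sample(c(1 / 3, 2 / 3), nrow(sites), replace = TRUE),
        cn == 1L ~ sample(c(error_rate, 1 - error_rate), nrow(sites),
                          replace = TRUE),
        TRUE ~ 0.5
      )
      n[cn == 0L] <- 0L
      alt <- rbinom(nrow(sites), n, p)
      tibble::tibble(sample = sid, chrom = sites$chrom, pos = sites$pos,
                     ref_count = n - alt, alt_count = alt)
    })
    cohort$snp_counts <- dplyr::bind_rows(per_sample)
    cohort
  })
}

#' Derive a gold-standard "array" call set from truth events
#'
#' Emulates how a chromosomal microarray would report the simulated truth:
#' focal events at or above the platform's minimum reportable size are
#' emitted once with endpoints independently perturbed by up to
#' `breakpoint_jitter_bp` (array probes do not land exactly on the
#' sequencing breakpoints); whole-chromosome aneuploidies are excluded
#' (arrays report those as karyotype-level findings, not interval calls).
#'
#' @param truth Tibble of expanded truth events (a cohort's `$truth`).
#' @param breakpoint_jitter_bp Maximum endpoint perturbation, bp.
#' @param min_size_bp Minimum reported event size (default 10 kb, a
#'   typical clinical array cutoff).
#' @param seed Integer seed.
#' @return Tibble of array calls sorted by sample, chromosome, start, with
#'   the source columns `copy_number`, `mosaic_fraction`, `class` kept.
#' @export
derive_array_callset <- function(truth, breakpoint_jitter_bp = 2000,
                                 min_size_bp = 10000, seed = 1) {
  if (breakpoint_jitter_bp < 0) abort("jitter must be >= 0")
  focal <- truth |>
    dplyr::filter(.data$class != "aneuploidy",
                  .data$end - .data$start >= min_size_bp)
  with_seed(seed, {
    if (nrow(focal) > 0) {
      j1 <- round(runif(nrow(focal), -breakpoint_jitter_bp,
                        breakpoint_jitter_bp))
      j2 <- round(runif(nrow(focal), -breakpoint_jitter_bp,
                        breakpoint_jitter_bp))
      focal$start <- pmax(0, focal$start + j1)
      focal$end <- pmax(focal$start + 1, focal$end + j2)
    }
    focal |>
      dplyr::arrange(.data$sample, .data$chrom, .data$start)
  })
}
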