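#' Adjusted per-chromosome read counts
#'
#' Counts reads per chromosome inside capture windows only, then rescales
#' each sample by \eqn{k_s = \bar T / T_s} (the cohort mean total over the
#' sample's total) so that every sample's adjusted total is the common
#' mean. Global depth differences between samples cancel exactly; what
#' remains is each chromosome's share of the sample's reads.
#'
#' @param counts Wide counts tibble (`chrom`, `start`, `end`,
#'   `window_id`, then samples).
#' @return A `wescnv_chrom_table` tibble: `sample`, `chrom`, `adjusted`
#'   with attribute `k` (named per-sample scale factors).
#' @export
adjusted_chromosome_counts <- function(counts) {
  mat <- counts_matrix(counts)
  totals <- colSums(mat)
  if (any(totals == 0)) {
    abort(paste0("sample(s) with zero total counts: ",
                 paste(names(totals)[totals == 0], collapse = ", ")))
  }
  k <- mean(totals) / totals
  per_chrom <- rowsum(mat, counts$chrom, reorder = FALSE)
  adj <- sweep(per_chrom, 2, k, `*`)
  out <- tibble::as_tibble(adj, rownames = "chrom") |>
    tidyr::pivot_longer(-"chrom", names_to = "sample",
                        values_to = "adjusted") |>
    dplyr::relocate("sample", "chrom")
  out <- tibble::new_tibble(out, class = "wescnv_chrom_table")
  attr(out, "k") <- k
  out
}

#' Per-chromosome coverage ratios across a cohort
#'
#' For each chromosome, each sample's adjusted count is divided by the
#' cross-sample mean adjusted count for that chromosome, so a diploid
#' chromosome sits near ratio 1, a trisomy near 1.5, and a mosaic loss of
#' a single-copy chromosome at \eqn{1 - f}. For chrX and chrY the mean is
#' taken within the sample's sex group when `sex_stratify` is on; sex is
#' taken from `sexes` if given, otherwise inferred from the chrY share of
#' reads (a sample is male when its chrY share exceeds half the
#' male-typical share, taken as the cohort maximum when the cohort spans
#' both sexes).
#'
#' @param table A `wescnv_chrom_table` from
#'   [adjusted_chromosome_counts()].
#' @param sexes Optional named (`"M"`/`"F"`) vector per sample.
#' @param sex_stratify Stratify chrX/chrY ratios by sex (default `TRUE`).
#' @param exclude_test Leave each sample out of the cross-sample mean in
#'   its own denominator (default `FALSE`: the mean includes the sample,
#'   so the cohort-mean ratio per chromosome is exactly 1, at the cost
#'   of a small self-damping of true outliers).
#' @return The table with columns `ratio` and `sex` added.
#' @export
chromosome_ratios <- function(table, sexes = NULL, sex_stratify = TRUE,
                              exclude_test = FALSE) {
  assert_columns(table, c("sample", "chrom", "adjusted"), "chromosome table")
  samples <- unique(table$sample)
  if (length(samples) < 3) abort("need >= 3 samples for cohort ratios")
  if (is.null(sexes)) {
    sexes <- infer_sex(table)
  } else {
    if (is.null(names(sexes))) names(sexes) <- samples
    if (!all(samples %in% names(sexes))) abort("`sexes` must cover all samples")
    sexes <- sexes[samples]
  }
  tab <- dplyr::mutate(table, sex = unname(sexes[.data$sample]))
  if (sex_stratify && any(tab$chrom %in% c("chrX", "chrY"))) {
    grp <- tab$chrom %in% c("chrX", "chrY")
    for (sx in unique(tab$sex[grp])) {
      n_grp <- length(unique(tab$sample[tab$sex == sx]))
      if (n_grp < 1) abort("empty sex group under stratification")
    }
    tab <- tab |>
      dplyr::group_by(.data$chrom,
                      grp_sex = dplyr::if_else(.data$chrom %in% c("chrX", "chrY"),
                                               .data$sex, "all")) |>
      dplyr::mutate(ratio = ratio_or_na(.data$adjusted, exclude_test)) |>
      dplyr::ungroup() |>
      dplyr::select(-"grp_sex")
  } else {
    tab <- tab |>
      dplyr::group_by(.data$chrom) |>
      dplyr::mutate(ratio = ratio_or_na(.data$adjusted, exclude_test)) |>
      dplyr::ungroup()
  }
  out <- tibble::new_tibble(tab, class = "wescnv_chrom_table")
  attr(out, "k") <- attr(table, "k")
  attr(out, "sexes") <- sexes
  out
}

ratio_or_na <- function(x, exclude_test = FALSE) {
  if (exclude_test && length(x) >= 2) {
    m <- (sum(x) - x) / (length(x) - 1)
    return(ifelse(m > 0, x / m, NA_real_))
  }
  m <- mean(x)
  if (m <= 0) return(rep(NA_real_, length(x)))
  x / m
}

# Infer sex from the chrY share of adjusted reads. With both sexes
# present the shares are strongly bimodal (female chrY capture is near
# zero); with a single-sex cohort the spread is small and everyone gets
# the same label.
infer_sex <- function(table) {
  samples <- unique(table$sample)
  if (!"chrY" %in% table$chrom) {
    return(setNames(rep("F", length(samples)), samples))
  }
  share <- table |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(y_share = sum(.data$adjusted[.data$chrom == "chrY"]) /
                       sum(.data$adjusted)) |>
    tibble::deframe()
  share <- share[samples]
  hi <- max(share)
  lo <- min(share)
  if (hi > 5 * (lo + 1e-9)) {
    sex <- ifelse(share > hi / 2, "M", "F")
  } else {
    # single-sex cohort: males if anyone has appreciable chrY coverage
    sex <- rep(if (hi > 1e-3) "M" else "F", length(samples))
  }
  setNames(sex, samples)
}

#' Grubbs critical value
#'
#' Two-sided critical value for the single-outlier Grubbs test:
#' \eqn{G_{crit} = \frac{N-1}{\sqrt N}\sqrt{t^2 / (N - 2 + t^2)}} with
#' \eqn{t} the upper \eqn{\alpha/(2N)} quantile of Student's t with
#' \eqn{N - 2} degrees of freedom.
#'
#' @param n Sample size (`>= 3`).
#' @param alpha Significance level.
#' @return Critical value(s), vectorized over `n`.
#' @export
grubbs_critical <- function(n, alpha = 0.05) {
  if (any(n < 3)) abort("Grubbs test needs N >= 3")
  t <- qt(1 - alpha / (2 * n), df = n - 2)
  ((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))
}

#' Grubbs outlier test
#'
#' Two-sided single-outlier test: \eqn{G = \max_i |x_i - \bar x| / s}
#' compared against [grubbs_critical()]. With `iterative = TRUE` a
#' detected outlier is removed and the test repeated on the remainder, so
#' two aberrant samples do not mask each other, until no rejection or 10%
#' of the values have been removed. Zero-variance input returns no
#' outlier with `G = 0`.
#'
#' @param values Numeric vector (`N >= 3`).
#' @param alpha Significance level.
#' @param iterative Repeat after removing each detected outlier.
#' @param max_remove_frac Cap on the fraction of values removable by
#'   iteration.
#' @return List: `outlier` (logical per value), `G`, `G_crit` (first
#'   iteration), `iterations` (tibble: `index`, `value`, `G`, `G_crit`).
#' @export
grubbs_test <- function(values, alpha = 0.05, iterative = TRUE,
                        max_remove_frac = 0.1) {
  n0 <- length(values)
  if (n0 < 3) abort("Grubbs test needs N >= 3")
  outlier <- rep(FALSE, n0)
  active <- which(!is.na(values))
  iters <- list()
  g1 <- NULL
  gc1 <- NULL
  max_remove <- max(1, floor(n0 * max_remove_frac))
  repeat {
    x <- values[active]
    s <- stats::sd(x)
    if (length(x) < 3 || is.na(s) || s == 0) {
      if (is.null(g1)) { g1 <- 0; gc1 <- grubbs_critical(max(n0, 3), alpha) }
      break
    }
    dev <- abs(x - mean(x))
    g <- max(dev) / s
    gc <- grubbs_critical(length(x), alpha)
    if (is.null(g1)) { g1 <- g; gc1 <- gc }
    if (g <= gc || sum(outlier) >= max_remove) break
    i <- active[which.max(dev)]
    outlier[i] <- TRUE
    iters[[length(iters) + 1L]] <-
      tibble::tibble(index = i, value = values[i], G = g, G_crit = gc)
    active <- setdiff(active, i)
    if (!iterative) break
  }
  list(outlier = outlier, G = g1, G_crit = gc1,
       iterations = dplyr::bind_rows(iters))
}

#' Mosaic fraction from a coverage ratio
#'
#' Inverts the dosage relation between the coverage ratio and the
#' fraction of cells carrying a one-copy gain or loss. On a diploid
#' baseline, a mosaic fraction \eqn{f} moves the ratio to
#' \eqn{1 \pm f/2}, so \eqn{\hat f = 2|\rho - 1|}; on a haploid baseline
#' (male chrY) a loss in fraction \eqn{f} gives ratio \eqn{1 - f}, so
#' \eqn{\hat f = |1 - \rho|}. Clipped to `[0, 1]`; a constitutional
#' trisomy or monosomy reports \eqn{f = 1}.
#'
#' @param ratio Coverage ratio(s) `>= 0`.
#' @param ploidy Baseline ploidy, 1 or 2.
#' @return Estimated mosaic fraction(s) in `[0, 1]`.
#' @examples
#' estimate_mosaic_fraction(0.5, ploidy = 1)  # 0.5 (mosaic loss of Y)
#' estimate_mosaic_fraction(1.5, ploidy = 2)  # 1   (constitutional trisomy)
#' @export
estimate_mosaic_fraction <- function(ratio, ploidy = 2) {
  if (any(ratio < 0, na.rm = TRUE)) abort("ratio must be >= 0")
  if (!all(ploidy %in% c(1, 2))) abort("baseline ploidy must be 1 or 2")
  f <- ifelse(ploidy == 2, 2 * abs(ratio - 1), abs(ratio - 1))
  clip(f, 0, 1)
}

#' Detect aneuploidy and chromosomal mosaicism across a cohort
#'
#' Runs the full ploidy analysis: capture-restricted adjusted chromosome
#' counts, cross-sample coverage ratios (sex-stratified for chrX/chrY),
#' a per-chromosome Grubbs outlier test, integer copy-number prediction
#' `round(ploidy * ratio)` clipped to `[0, 4]`, and a mosaic-fraction
#' estimate. A sample is reported aneuploid on a chromosome when it is
#' the Grubbs outlier *and* its estimated mosaic fraction reaches
#' `mosaic_min` — the magnitude gate keeps the per-chromosome false-alarm
#' rate of the bare Grubbs test (which is \eqn{\alpha} by construction)
#' from surfacing trivially small deviations as findings.
#'
#' @param counts Wide counts tibble.
#' @param sexes Optional `"M"`/`"F"` per sample (named or in column
#'   order); inferred from chrY coverage if omitted.
#' @param alpha Grubbs significance level.
#' @param iterative Iterative Grubbs re-testing.
#' @param sex_stratify Stratify chrX/chrY by sex.
#' @param mosaic_min Minimum mosaic fraction to report a finding.
#' @param exclude_test Leave-one-out cross-sample mean (see
#'   [chromosome_ratios()]).
#' @return A `wescnv_aneuploidy` tibble: `sample`, `chrom`, `sex`,
#'   `ratio`, `G`, `G_crit`, `outlier`, `predicted_cn`,
#'   `mosaic_fraction`, `is_aneuploidy`.
#' @export
detect_aneuploidy <- function(counts, sexes = NULL, alpha = 0.05,
                              iterative = TRUE, sex_stratify = TRUE,
                              mosaic_min = 0.2, exclude_test = FALSE) {
  adj <- adjusted_chromosome_counts(counts)
  rat <- chromosome_ratios(adj, sexes = sexes, sex_stratify = sex_stratify,
                           exclude_test = exclude_test)
  rat$ploidy <- dplyr::case_when(
    rat$chrom == "chrY" & rat$sex == "M" ~ 1,
    rat$chrom == "chrY" & rat$sex == "F" ~ NA_real_,
    rat$chrom == "chrX" & rat$sex == "M" ~ 1,
    TRUE ~ 2
  )
  grouped <- rat |>
    dplyr::group_by(.data$chrom,
                    grp_sex = dplyr::if_else(
                      sex_stratify & .data$chrom %in% c("chrX", "chrY"),
                      .data$sex, "all"))
  out <- grouped |>
    dplyr::group_modify(function(df, key) {
      usable <- !is.na(df$ratio) & !is.na(df$ploidy)
      df$G <- NA_real_
      df$G_crit <- NA_real_
      df$outlier <- FALSE
      if (sum(usable) >= 3) {
        g <- grubbs_test(ifelse(usable, df$ratio, NA_real_), alpha = alpha,
                         iterative = iterative)
        df$G <- g$G
        df$G_crit <- g$G_crit
        df$outlier <- g$outlier
      }
      df
    }) |>
    dplyr::ungroup() |>
    dplyr::select(-"grp_sex")
  out <- out |>
    dplyr::mutate(
      predicted_cn = ifelse(
        is.na(.data$ratio) | is.na(.data$ploidy), NA_integer_,
        as.integer(clip(round_half_up(.data$ploidy * .data$ratio), 0, 4))),
      mosaic_fraction = ifelse(
        is.na(.data$ratio) | is.na(.data$ploidy), NA_real_,
        estimate_mosaic_fraction(pmax(.data$ratio, 0),
                                 ploidy = ifelse(is.na(.data$ploidy), 2,
                                                 .data$ploidy))),
      is_aneuploidy = !is.na(.data$outlier) & .data$outlier &
        !is.na(.data$mosaic_fraction) & .data$mosaic_fraction >= mosaic_min
    ) |>
    dplyr::arrange(match(.data$chrom, unique(counts$chrom)), .data$sample) |>
    dplyr::select("sample", "chrom", "sex", "ratio", "G", "G_crit",
                  "outlier", "predicted_cn", "mosaic_fraction",
                  "is_aneuploidy")
  tibble::new_tibble(out, class = "wescnv_aneuploidy")
}

#' Karyotype-style summary lines for detected aneuploidies
#'
#' @param result A `wescnv_aneuploidy` tibble.
#' @return Character vector like `"S3 chr21x3 (ratio 1.49, f = 1.00)"`;
#'   empty when nothing was detected.
#' @export
karyotype_summary <- function(result) {
  hits <- dplyr::filter(result, .data$is_aneuploidy)
  if (nrow(hits) == 0) return(character())
  sprintf("%s %sx%d (ratio %.2f, f = %.2f)", hits$sample, hits$chrom,
          hits$predicted_cn, hits$ratio, hits$mosaic_fraction)
}
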