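#' Beta-binomial log density
#'
#' Parameterized by mean fraction `f` and overdispersion `theta`, with
#' shape parameters `a = f (1 - theta) / theta`,
#' `b = (1 - f)(1 - theta) / theta`; `theta = 0` degenerates to the
#' binomial. Used as the emission density of the copy-number HMM: the
#' test-sample count `y` out of `n = y + r` total (test + reference)
#' reads in a window.
#'
#' @param y Successes (test reads).
#' @param n Trials (test + reference reads).
#' @param f Mean fraction in (0, 1).
#' @param theta Overdispersion `>= 0`.
#' @return Log density, vectorized over `y`, `n`, `f`.
#' @export
dbetabinom_log <- function(y, n, f, theta) {
  if (any(theta < 0)) abort("`theta` must be >= 0")
  if (all(theta == 0)) return(dbinom(y, n, f, log = TRUE))
  a <- f * (1 - theta) / theta
  b <- (1 - f) * (1 - theta) / theta
  lchoose(n, y) + lbeta(y + a, n - y + b) - lbeta(a, b)
}

#' Select a reference sample set for one test sample
#'
#' Ranks all other samples by the Pearson correlation of log-transformed,
#' total-normalized window-count profiles with the test sample
#' (correlation ties broken by sample id order), then adds members
#' greedily in rank order as long as the predicted variance of the test
#' read fraction under a beta-binomial with the current overdispersion
#' estimate keeps decreasing, up to `max_members`. A well-matched
#' aggregate reference is the main determinant of calling sensitivity:
#' dissimilar members inflate the overdispersion faster than the extra
#' counts shrink the binomial noise, which is when accrual stops.
#'
#' Candidates whose chrY coverage class differs from the test sample's
#' are excluded first (when the counts contain chrY windows): a
#' male/female-mismatched background turns every chrY window into a
#' spurious whole-arm call, and samples "with similar read count
#' distributions" are by construction same-sex on chrY. If fewer than
#' one same-class candidate exists, all candidates are kept.
#'
#' @param counts Wide counts tibble (`chrom`, `start`, `end`,
#'   `window_id`, then one column per sample), as in a cohort's
#'   `$counts`.
#' @param test Test sample id (a column of `counts`).
#' @param max_members Maximum reference members (default 10).
#' @return A `wescnv_reference` list: `test`, `members`, `r` (aggregated
#'   member counts per window), `scores` (tibble of per-candidate
#'   correlations), `window_id`.
#' @export
select_reference <- function(counts, test, max_members = 10) {
  mat <- counts_matrix(counts)
  if (!test %in% colnames(mat)) abort("test sample not found in counts")
  if (ncol(mat) < 2) abort("cannot build background: cohort has < 2 samples")
  others <- setdiff(colnames(mat), test)
  is_y <- counts$chrom == "chrY"
  if (any(is_y) && !all(is_y)) {
    share <- colSums(mat[is_y, , drop = FALSE]) / colSums(mat)
    if (max(share) > 5 * (min(share) + 1e-9)) {  # cohort spans both classes
      cls <- share > max(share) / 2  # TRUE = appreciable chrY coverage
      same <- others[cls[others] == cls[test]]
      if (length(same) >= 1) others <- same
    }
  }
  logprof <- function(v) log((v + 0.5) / sum(v))
  y <- mat[, test]
  ly <- logprof(y)
  cors <- vapply(others, function(s) cor(ly, logprof(mat[, s])), numeric(1))
  ranked <- others[order(-cors, match(others, colnames(mat)))]

  pred_var <- function(r) {
    n <- y + r
    keep <- n > 0
    p <- fit_emission_params(y[keep], r[keep], counts$chrom[keep])
    mean(p$phi * (1 - p$phi) * (1 + (n[keep] - 1) * p$theta) / n[keep])
  }
  members <- ranked[1]
  r <- mat[, ranked[1]]
  best <- pred_var(r)
  for (s in ranked[-1]) {
    if (length(members) >= max_members) break
    cand <- r + mat[, s]
    v <- pred_var(cand)
    if (v < best) {
      members <- c(members, s)
      r <- cand
      best <- v
    } else break
  }
  structure(
    list(test = test, members = members, r = unname(r),
         scores = tibble::tibble(sample = others, correlation = cors),
         window_id = counts$window_id),
    class = "wescnv_reference"
  )
}

#' @export
print.wescnv_reference <- function(x, ...) {
  cat("<wescnv_reference> test ", x$test, ": ", length(x$members),
      " member(s): ", paste(x$members, collapse = ", "), "\n", sep = "")
  invisible(x)
}

counts_matrix <- function(counts) {
  assert_columns(counts, c("chrom", "start", "end", "window_id"), "counts")
  meta <- c("chrom", "start", "end", "window_id")
  m <- as.matrix(counts[, setdiff(names(counts), meta)])
  if (any(m < 0)) abort("read counts must be non-negative")
  storage.mode(m) <- "double"
  m
}

#' Fit the beta-binomial emission parameters
#'
#' The expected diploid test count in window \eqn{w} is
#' \eqn{\hat y_w = r_w \cdot \Sigma y / \Sigma r} (reference count scaled
#' by the global test/reference depth ratio), giving the expected diploid
#' test-read fraction \eqn{\phi_w = \hat y_w / (\hat y_w + r_w)}. The
#' overdispersion \eqn{\theta} is estimated by the method of moments from
#' the excess variance of \eqn{y_w} around
#' \eqn{\mathrm{Binomial}(n_w, \phi_w)} across (autosomal, if `chrom` is
#' given) windows, floored at 0.
#'
#' @param y Test counts per window.
#' @param r Aggregated reference counts per window (same order).
#' @param chrom Optional chromosome labels; when given, `theta` is
#'   estimated from autosomes only (chrX/chrY excluded).
#' @return A `wescnv_emission` list: `phi` (per window), `theta`,
#'   `n_windows`, `depth_ratio`.
#' @export
fit_emission_params <- function(y, r, chrom = NULL) {
  if (length(y) != length(r)) abort("y and r must have equal length")
  if (sum(y) == 0 || sum(r) == 0) abort("zero total counts")
  ratio <- sum(y) / sum(r)
  phi <- (r * ratio) / (r * ratio + r)
  phi[r == 0] <- ratio / (1 + ratio)

  est <- seq_along(y)
  if (!is.null(chrom)) est <- which(!chrom %in% c("chrX", "chrY"))
  n <- y + r
  use <- est[n[est] >= 2]
  num <- sum((y[use] - n[use] * phi[use])^2 - n[use] * phi[use] * (1 - phi[use]))
  den <- sum(n[use] * phi[use] * (1 - phi[use]) * (n[use] - 1))
  theta <- max(0, num / den)
  structure(
    list(phi = phi, theta = theta, n_windows = length(y),
         depth_ratio = ratio),
    class = "wescnv_emission"
  )
}

#' @export
print.wescnv_emission <- function(x, ...) {
  cat("<wescnv_emission> ", x$n_windows, " windows, theta = ",
      signif(x$theta, 4), ", depth ratio = ", signif(x$depth_ratio, 4),
      "\n", sep = "")
  invisible(x)
}

#' Expected test-read fraction under a copy-number state
#'
#' Dosage arithmetic for the likelihood ratio: if the diploid expected
#' test fraction is \eqn{\phi}, a copy-number state \eqn{c} scales the
#' test odds by \eqn{c/2}, giving
#' \eqn{f = (c/2)\phi / ((c/2)\phi + 1 - \phi)}, floored at
#' \eqn{10^{-4}} so the homozygous-deletion state keeps a proper density.
#'
#' @param phi Diploid expected test fraction(s) in (0, 1).
#' @param c Copy number `>= 0`.
#' @return Expected fraction(s) under state `c`.
#' @examples
#' state_fraction(0.5, 1)  # 1/3
#' state_fraction(0.5, 3)  # 3/5
#' @export
state_fraction <- function(phi, c) {
  if (any(c < 0)) abort("copy number must be >= 0")
  num <- (c / 2) * phi
  pmax(num / (num + (1 - phi)), 1e-4)
}

# Viterbi decoding of a K-state HMM from log-emission matrix (W x K).
viterbi_decode <- function(log_emis, log_trans, log_init) {
  w <- nrow(log_emis)
  k <- ncol(log_emis)
  delta <- matrix(-Inf, w, k)
  psi <- matrix(0L, w, k)
  delta[1, ] <- log_init + log_emis[1, ]
  if (w > 1) {
    for (t in 2:w) {
      cand <- delta[t - 1, ] + log_trans       # k x k: from row, to col
      psi[t, ] <- max.col(t(cand), ties.method = "first")
      delta[t, ] <- cand[cbind(psi[t, ], seq_len(k))] + log_emis[t, ]
    }
  }
  path <- integer(w)
  path[w] <- which.max(delta[w, ])
  if (w > 1) for (t in (w - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  path
}

hmm_log_trans <- function(q, L) {
  if (q <= 0 || q >= 0.5) abort("`q` must be in (0, 0.5)")
  if (L < 1) abort("`L` must be >= 1")
  # states: 1 = CN1, 2 = CN2 (diploid), 3 = CN3
  leave <- 1 / L
  tr <- matrix(c(
    1 - leave, leave,     0,
    q / 2,     1 - q,     q / 2,
    0,         leave,     1 - leave
  ), nrow = 3, byrow = TRUE)
  log(tr)
}

#' Call focal CNVs for one test sample
#'
#' Segments each chromosome with a 3-state HMM over copy-number states
#' {1, 2, 3}: the diploid state persists with probability `1 - q` per
#' window and CNV states with `1 - 1/L` (expected CNV length `L`
#' windows); emissions are beta-binomial
#' \eqn{BB(y_w; n_w, f_w(c), \theta)} with `f_w(c)` from
#' [state_fraction()]. The Viterbi path is decoded and maximal runs of
#' non-diploid states become calls. Each call is scored with a Bayes
#' factor: the log10 likelihood ratio of its copy-number state to the
#' diploid state summed over its windows. Windows with `n_w = 0` carry no
#' evidence and contribute 0. Calls whose observed depth ratio falls
#' below `zero_ratio_threshold` are relabeled homozygous (CN 0). Calls
#' never span chromosome boundaries.
#'
#' @param counts Wide counts tibble (see [select_reference()]).
#' @param test Test sample id.
#' @param reference A `wescnv_reference` for `test` built on the same
#'   windows.
#' @param params Optional `wescnv_emission`; fitted from `test` and the
#'   reference if omitted.
#' @param q Per-window probability of leaving the diploid state.
#' @param L Expected CNV length in windows.
#' @param zero_ratio_threshold Observed-ratio cutoff below which a
#'   deletion call is relabeled CN 0.
#' @return A `wescnv_calls` tibble: `sample`, `chrom`, `start`, `end`,
#'   `cn`, `bayes_factor`, `n_windows`, `observed_ratio`.
#' @export
call_cnvs <- function(counts, test, reference = NULL, params = NULL,
                      q = 1e-4, L = 50, zero_ratio_threshold = 0.15) {
  if (is.null(reference)) reference <- select_reference(counts, test)
  if (!identical(reference$window_id, counts$window_id)) {
    abort("reference was built on a different window set")
  }
  if (reference$test != test) abort("reference was built for another sample")
  mat <- counts_matrix(counts)
  y <- mat[, test]
  r <- reference$r
  if (is.null(params)) params <- fit_emission_params(y, r, counts$chrom)
  if (length(params$phi) != length(y)) {
    abort("emission params were fitted on a different window set")
  }
  n <- y + r
  phi <- params$phi
  theta <- params$theta
  states <- c(1, 2, 3)
  log_emis <- vapply(states, function(c) {
    le <- dbetabinom_log(y, n, state_fraction(phi, c), theta)
    le[n == 0] <- 0
    le
  }, numeric(length(y)))
  log_trans <- hmm_log_trans(q, L)
  log_init <- log(c(q / 2, 1 - q, q / 2))

  calls <- purrr::map(split(seq_along(y), counts$chrom), function(idx) {
    idx <- idx[order(counts$start[idx])]
    path <- viterbi_decode(log_emis[idx, , drop = FALSE], log_trans, log_init)
    runs <- rle(path)
    stops <- cumsum(runs$lengths)
    starts <- stops - runs$lengths + 1L
    keep <- which(runs$values != 2L)
    purrr::map(keep, function(k) {
      win <- idx[starts[k]:stops[k]]
      st <- states[runs$values[k]]
      bf <- sum((log_emis[win, runs$values[k]] - log_emis[win, 2L]) / log(10))
      obs <- observed_ratio(y[win], r[win], phi[win])
      tibble::tibble(
        sample = test,
        chrom = counts$chrom[win[1]],
        start = min(counts$start[win]),
        end = max(counts$end[win]),
        cn = if (st == 1 && !is.na(obs) && obs < zero_ratio_threshold) 0L
             else as.integer(st),
        bayes_factor = bf,
        n_windows = length(win),
        observed_ratio = obs
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  if (nrow(calls) == 0) {
    calls <- tibble::tibble(sample = character(), chrom = character(),
                            start = numeric(), end = numeric(),
                            cn = integer(), bayes_factor = numeric(),
                            n_windows = integer(), observed_ratio = numeric())
  }
  calls <- dplyr::arrange(calls, match(.data$chrom, unique(counts$chrom)),
                          .data$start)
  tibble::new_tibble(calls, class = "wescnv_calls")
}

# observed / expected-diploid depth: the expected diploid test count in a
# window is the reference count scaled by the fitted depth odds,
# r_w * phi / (1 - phi).
observed_ratio <- function(y, r, phi) {
  keep <- r > 0
  if (!any(keep)) return(NA_real_)
  expected <- r[keep] * phi[keep] / (1 - phi[keep])
  mean(y[keep] / expected)
}

#' Observed depth ratio and integer CN label for a call region
#'
#' The observed ratio is the mean over the call's windows of the test
#' count divided by its expected diploid count \eqn{\phi_w n_w}; the CN
#' label is `round(2 * ratio)` clipped to `[0, 4]` (half rounds away from
#' zero). A constitutional heterozygous deletion sits near 0.5, a
#' duplication near 1.5, and mosaics in between (e.g. a 25% mosaic
#' deletion at 0.875).
#'
#' @param call One-row data frame with `chrom`, `start`, `end`.
#' @param counts Wide counts tibble.
#' @param test Test sample id.
#' @param reference `wescnv_reference` on the same windows.
#' @param params Optional fitted `wescnv_emission`.
#' @return Tibble with `observed_ratio` and `cn_label`.
#' @export
genotype_ratio <- function(call, counts, test, reference, params = NULL) {
  mat <- counts_matrix(counts)
  y <- mat[, test]
  r <- reference$r
  if (is.null(params)) params <- fit_emission_params(y, r, counts$chrom)
  hit <- counts$chrom == call$chrom[1] & counts$end > call$start[1] &
    counts$start < call$end[1]
  if (!any(hit)) abort("call windows not found in counts")
  ratio <- observed_ratio(y[hit], r[hit], params$phi[hit])
  tibble::tibble(
    observed_ratio = ratio,
    cn_label = as.integer(clip(round_half_up(2 * ratio), 0, 4))
  )
}

#' Call CNVs for every sample in a cohort
#'
#' Convenience wrapper: builds a reference set and emission fit per
#' sample and binds all calls.
#'
#' @inheritParams call_cnvs
#' @param max_members Passed to [select_reference()].
#' @return A `wescnv_calls` tibble over all samples.
#' @export
call_cohort <- function(counts, max_members = 10, q = 1e-4, L = 50,
                        zero_ratio_threshold = 0.15) {
  samples <- setdiff(names(counts), c("chrom", "start", "end", "window_id"))
  out <- purrr::map(samples, function(s) {
    ref <- select_reference(counts, s, max_members = max_members)
    call_cnvs(counts, s, ref, q = q, L = L,
              zero_ratio_threshold = zero_ratio_threshold)
  }) |> dplyr::bind_rows()
  tibble::new_tibble(out, class = "wescnv_calls")
}
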