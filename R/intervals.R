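#' Interval arithmetic on genomic spans
#'
#' All coordinates inside the package are 0-based half-open (BED
#' convention): an interval covers bases `start .. end - 1` and its length
#' is `end - start`. On-disk TSV formats are 1-based inclusive; the readers
#' and writers in [read_calls_tsv()] perform the conversion, so intervals
#' printed in clinical reports (1-based inclusive) gain the same basepair
#' length after conversion.
#'
#' `jaccard_similarity()` computes the basepair Jaccard coefficient
#' between two interval sets row by row: intersection length divided by
#' union length, where the union of two disjoint intervals is the sum of
#' their lengths. Intervals on different chromosomes have similarity 0.
#'
#' @param a,b Data frames with columns `chrom`, `start`, `end`
#'   (0-based half-open). Rows are paired; a 1-row frame is recycled
#'   against a longer one.
#' @return For `jaccard_similarity()` and `reciprocal_overlap()`, a
#'   numeric vector in `[0, 1]`, one value per row pair. For
#'   `overlap_bp()`, a non-negative integer vector of overlap lengths.
#' @examples
#' a <- tibble::tibble(chrom = "chr7", start = 72643630, end = 74142190)
#' b <- tibble::tibble(chrom = "chr7", start = 72717453, end = 74133478)
#' jaccard_similarity(a, b)  # ~0.945
#' @export
jaccard_similarity <- function(a, b) {
  p <- pair_intervals(a, b)
  ov <- overlap_len(p$s1, p$e1, p$s2, p$e2)
  un <- (p$e1 - p$s1) + (p$e2 - p$s2) - ov
  out <- ifelse(p$c1 == p$c2 & un > 0, ov / un, 0)
  as.numeric(out)
}

#' @rdname jaccard_similarity
#' @export
overlap_bp <- function(a, b) {
  p <- pair_intervals(a, b)
  as.numeric(ifelse(p$c1 == p$c2, overlap_len(p$s1, p$e1, p$s2, p$e2), 0))
}

#' @rdname jaccard_similarity
#' @export
reciprocal_overlap <- function(a, b) {
  p <- pair_intervals(a, b)
  ov <- ifelse(p$c1 == p$c2, overlap_len(p$s1, p$e1, p$s2, p$e2), 0)
  as.numeric(pmin(ov / (p$e1 - p$s1), ov / (p$e2 - p$s2)))
}

overlap_len <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

pair_intervals <- function(a, b) {
  assert_columns(a, c("chrom", "start", "end"), "interval set `a`")
  assert_columns(b, c("chrom", "start", "end"), "interval set `b`")
  if (any(a$end <= a$start) || any(b$end <= b$start)) {
    abort("interval with end <= start (0-based half-open spans need end > start)")
  }
  n <- max(nrow(a), nrow(b))
  if (!(nrow(a) %in% c(1L, n)) || !(nrow(b) %in% c(1L, n))) {
    abort("interval sets must have equal row counts (or one must be 1 row)")
  }
  idx_a <- if (nrow(a) == 1L) rep(1L, n) else seq_len(n)
  idx_b <- if (nrow(b) == 1L) rep(1L, n) else seq_len(n)
  list(c1 = a$chrom[idx_a], s1 = a$start[idx_a], e1 = a$end[idx_a],
       c2 = b$chrom[idx_b], s2 = b$start[idx_b], e2 = b$end[idx_b])
}

# For every row of `x`, indices of rows of `y` on the same chromosome with
# >= min_bp overlap. Returns a list of integer vectors.
overlap_hits <- function(x, y, min_bp = 1) {
  purrr::map(seq_len(nrow(x)), function(i) {
    same <- which(y$chrom == x$chrom[i])
    if (length(same) == 0L) return(integer())
    ov <- overlap_len(x$start[i], x$end[i], y$start[same], y$end[same])
    same[ov >= min_bp]
  })
}
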