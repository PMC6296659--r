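#' Build a synthetic exome capture design
#'
#' Generates a sorted, non-overlapping set of capture targets (exon-sized
#' intervals) on a set of synthetic chromosomes, each target labeled with a
#' gene symbol and exon index. When `n_chromosomes >= 4` the last two
#' chromosomes are labeled `chrX` and `chrY` so sex-aware simulation and
#' ploidy analysis can be exercised; the rest are `chr1`, `chr2`, ...
#'
#' Target lengths vary around `target_length_bp` and inter-target gaps are
#' exponentially distributed with mean `mean_gap_bp`, mimicking the uneven
#' spacing of real capture designs. `mean_gap_bp` controls the physical
#' span of a chromosome, which matters when megabase-scale events must fit
#' on it.
#'
#' @param n_chromosomes Number of chromosomes (including chrX/chrY when
#'   `>= 4`).
#' @param targets_per_chromosome Capture targets per chromosome.
#' @param target_length_bp Mean target length in bp.
#' @param seed Integer seed; the design is a deterministic function of all
#'   four arguments.
#' @param mean_gap_bp Mean gap between consecutive targets in bp.
#' @param exons_per_gene Consecutive targets grouped under one synthetic
#'   gene symbol.
#' @param chry_frac Fraction of `targets_per_chromosome` allocated to
#'   chrY (default 0.05): exome designs capture far less of chrY than of
#'   an autosome, which keeps male/female library totals comparable.
#' @return A `capture_design`: a tibble with columns `chrom`, `start`,
#'   `end` (0-based half-open), `gene`, `exon`, carrying a
#'   `chrom_lengths` attribute (named numeric, bp).
#' @examples
#' d <- make_capture_design(2, 20, 200, seed = 1)
#' attr(d, "chrom_lengths")
#' @export
make_capture_design <- function(n_chromosomes, targets_per_chromosome,
                                target_length_bp, seed,
                                mean_gap_bp = 2000, exons_per_gene = 5,
                                chry_frac = 0.05) {
  for (arg in list(n_chromosomes, targets_per_chromosome, target_length_bp)) {
    if (!is_count(arg)) abort("counts and lengths must be positive integers")
  }
  chroms <- if (n_chromosomes >= 4) {
    c(paste0("chr", seq_len(n_chromosomes - 2L)), "chrX", "chrY")
  } else {
    paste0("chr", seq_len(n_chromosomes))
  }
  with_seed(seed, {
    per_chrom <- purrr::map(seq_along(chroms), function(ci) {
      n <- if (chroms[ci] == "chrY") {
        max(2L, round(chry_frac * targets_per_chromosome))
      } else {
        targets_per_chromosome
      }
      lens <- pmax(50, round(rnorm(n, target_length_bp, target_length_bp / 4)))
      gaps <- pmax(20, round(rexp(n, 1 / mean_gap_bp)))
      starts <- cumsum(gaps) + cumsum(dplyr::lag(lens, default = 0))
      gene_idx <- (seq_len(n) - 1L) %/% exons_per_gene + 1L
      tibble::tibble(
        chrom = chroms[ci],
        start = starts,
        end = starts + lens,
        gene = paste0("GENE", ci, "_", gene_idx),
        exon = seq_len(n) - (gene_idx - 1L) * exons_per_gene
      )
    })
    regions <- dplyr::bind_rows(per_chrom)
    lengths <- regions |>
      dplyr::group_by(.data$chrom) |>
      dplyr::summarise(len = max(.data$end) + round(mean_gap_bp)) |>
      tibble::deframe()
    new_capture_design(regions, lengths[chroms])
  })
}

new_capture_design <- function(regions, chrom_lengths) {
  out <- tibble::new_tibble(regions, class = "capture_design")
  attr(out, "chrom_lengths") <- chrom_lengths
  out
}

#' Tile capture regions into fixed-width read-count windows
#'
#' Each capture region is split left-to-right into consecutive windows of
#' `window_bp`. A final remainder shorter than `window_bp` is kept as its
#' own window if it is at least `window_bp / 2`, otherwise merged into the
#' preceding window; a region shorter than `window_bp / 2` becomes a
#' single short window. Windows tile the regions exactly, with no gaps or
#' overlaps, and never cross region boundaries.
#'
#' @param design A `capture_design` (or any tibble with `chrom`, `start`,
#'   `end` and optionally `gene`, `exon`).
#' @param window_bp Window width in bp (default 100).
#' @return Tibble of windows: `chrom`, `start`, `end`, `window_id`,
#'   `gene`, `exon`, sorted by chromosome then start.
#' @export
bin_capture_regions <- function(design, window_bp = 100) {
  assert_columns(design, c("chrom", "start", "end"), "capture design")
  if (nrow(design) == 0) abort("capture design has no regions")
  if (!is_count(window_bp)) abort("`window_bp` must be a positive integer")
  has_gene <- all(c("gene", "exon") %in% names(design))
  widths <- lapply(design$end - design$start, function(len) {
    n_full <- len %/% window_bp
    rem <- len - n_full * window_bp
    w <- rep(window_bp, n_full)
    if (rem > 0) {
      if (rem >= window_bp / 2 || n_full == 0) {
        w <- c(w, rem)
      } else {
        w[n_full] <- w[n_full] + rem
      }
    }
    w
  })
  n_per <- lengths(widths)
  idx <- rep(seq_len(nrow(design)), n_per)
  w_flat <- unlist(widths)
  ends <- unlist(lapply(seq_len(nrow(design)), function(i) {
    design$start[i] + cumsum(widths[[i]])
  }))
  out <- tibble::tibble(
    chrom = design$chrom[idx],
    start = ends - w_flat,
    end = ends,
    gene = if (has_gene) design$gene[idx] else NA_character_,
    exon = if (has_gene) design$exon[idx] else NA_integer_
  )
  chrom_order <- unique(design$chrom)
  out <- dplyr::arrange(out, match(.data$chrom, chrom_order), .data$start)
  out$window_id <- sprintf("w%06d", seq_len(nrow(out)))
  dplyr::relocate(out, "chrom", "start", "end", "window_id")
}
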