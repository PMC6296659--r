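#' Classify detectability strata for gold-standard array calls
#'
#' Flags each array (gold) call with the strata used for stratified
#' sensitivity reporting:
#' * `potentially_detectable` — overlaps at least one capture window by
#'   >= 1 bp (a CNV entirely outside the capture cannot be seen by a
#'   read-depth exome method);
#' * `non_repeated` — no same-direction gold call in another sample at
#'   >= 50% reciprocal overlap (repeated calls mark polymorphic loci);
#' * `adequately_covered` — overlaps at least one exon target whose gene
#'   symbol does not match `uncharacterized_pattern`, and the
#'   cohort-median read depth over the overlapped windows is at least
#'   `min_depth`.
#'
#' @param gold Gold call tibble (`sample`, `chrom`, `start`, `end`,
#'   `copy_number` or `cn`).
#' @param design Capture design with gene annotation.
#' @param counts Wide counts tibble on the design's windows.
#' @param uncharacterized_pattern Regex matching uncharacterized gene
#'   symbols (default `"^LOC|pseudogene"`).
#' @param min_depth Minimum cohort-median window depth.
#' @param reciprocal Reciprocal-overlap threshold for the repeat flag.
#' @return `gold` with the three logical strata columns appended.
#' @export
classify_detectability <- function(gold, design, counts,
                                   uncharacterized_pattern = "^LOC|pseudogene",
                                   min_depth = 10, reciprocal = 0.5) {
  gold <- normalize_cn_column(gold)
  windows <- counts[, c("chrom", "start", "end")]
  mat <- counts_matrix(counts)
  med_depth <- apply(mat, 1, median)

  win_hits <- overlap_hits(gold, windows)
  gold$potentially_detectable <- vapply(win_hits, length, integer(1)) > 0

  has_gene <- "gene" %in% names(design)
  gold$adequately_covered <- vapply(seq_len(nrow(gold)), function(i) {
    ex <- overlap_hits(gold[i, ], design)[[1]]
    if (length(ex) == 0) return(FALSE)
    char_ok <- if (has_gene) {
      any(!grepl(uncharacterized_pattern, design$gene[ex]))
    } else TRUE
    w <- win_hits[[i]]
    char_ok && length(w) > 0 && median(med_depth[w]) >= min_depth
  }, logical(1))

  dir <- cn_direction(gold$cn)
  gold$non_repeated <- vapply(seq_len(nrow(gold)), function(i) {
    cand <- which(gold$sample != gold$sample[i] &
                    gold$chrom == gold$chrom[i] & dir == dir[i])
    if (length(cand) == 0) return(TRUE)
    all(reciprocal_overlap(gold[i, ], gold[cand, ]) < reciprocal)
  }, logical(1))
  gold
}

normalize_cn_column <- function(df) {
  if (!"cn" %in% names(df) && "copy_number" %in% names(df)) {
    df$cn <- df$copy_number
  }
  assert_columns(df, c("sample", "chrom", "start", "end", "cn"), "call set")
  df
}

#' Match gold-standard calls against WES calls
#'
#' A gold call is matched when some WES call in the same sample, on the
#' same chromosome and (by default) in the same direction overlaps it by
#' at least `min_overlap_bp`. The best match is the WES call with the
#' highest Jaccard similarity; one WES call may match several gold calls.
#'
#' @param gold Gold call tibble (optionally carrying strata flags from
#'   [classify_detectability()]).
#' @param wes WES call tibble (`sample`, `chrom`, `start`, `end`, `cn`).
#' @param same_direction Require deletion/duplication concordance.
#' @param min_overlap_bp Minimum overlap in bp.
#' @return A `wescnv_concordance` tibble: the gold columns plus
#'   `matched`, `jaccard`, `wes_start`, `wes_end`, `wes_cn`
#'   (`NA` when unmatched).
#' @export
match_calls <- function(gold, wes, same_direction = TRUE,
                        min_overlap_bp = 1) {
  gold <- normalize_cn_column(gold)
  wes <- normalize_cn_column(wes)
  gdir <- cn_direction(gold$cn)
  wdir <- cn_direction(wes$cn)
  res <- purrr::map(seq_len(nrow(gold)), function(i) {
    cand <- which(wes$sample == gold$sample[i] &
                    wes$chrom == gold$chrom[i] &
                    (!same_direction | wdir == gdir[i]))
    if (length(cand) > 0) {
      ov <- overlap_bp(gold[i, ], wes[cand, ])
      cand <- cand[ov >= min_overlap_bp]
    }
    if (length(cand) == 0) {
      return(tibble::tibble(matched = FALSE, jaccard = NA_real_,
                            wes_start = NA_real_, wes_end = NA_real_,
                            wes_cn = NA_integer_))
    }
    sims <- jaccard_similarity(gold[i, ], wes[cand, ])
    j <- cand[which.max(sims)]
    tibble::tibble(matched = TRUE, jaccard = max(sims),
                   wes_start = wes$start[j], wes_end = wes$end[j],
                   wes_cn = as.integer(wes$cn[j]))
  }) |> dplyr::bind_rows()
  out <- dplyr::bind_cols(gold, res)
  tibble::new_tibble(out, class = "wescnv_concordance")
}

#' Stratified sensitivity of WES calling against array gold standard
#'
#' Reports detected/total and percent sensitivity for deletions and
#' duplications in three nested strata: all potentially detectable gold
#' calls; those additionally unique to a single patient; and those
#' additionally covering characterized coding genes at usable depth.
#' Percentages are rounded half-up to one decimal; a stratum with zero
#' total reports `NA` rather than 0.
#'
#' @param rows A `wescnv_concordance` tibble carrying the strata flags.
#' @return Tibble: `stratum`, `direction`, `detected`, `total`,
#'   `percent`.
#' @export
stratified_sensitivity <- function(rows) {
  assert_columns(rows, c("matched", "cn", "potentially_detectable",
                         "non_repeated", "adequately_covered"),
                 "concordance rows")
  strata <- list(
    all_detectable = rows$potentially_detectable,
    non_repeated = rows$potentially_detectable & rows$non_repeated,
    non_repeated_covered = rows$potentially_detectable & rows$non_repeated &
      rows$adequately_covered
  )
  dir <- cn_direction(rows$cn)
  grid <- tidyr::expand_grid(stratum = names(strata),
                             direction = c("del", "dup"))
  purrr::pmap(grid, function(stratum, direction) {
    keep <- strata[[stratum]] & dir == direction
    total <- sum(keep)
    detected <- sum(keep & rows$matched)
    tibble::tibble(
      stratum = stratum, direction = direction,
      detected = detected, total = total,
      percent = if (total == 0) NA_real_
                else round_half_up(100 * detected / total, 1)
    )
  }) |> dplyr::bind_rows()
}

#' Sensitivity from raw detected/total counts
#'
#' The arithmetic used in sensitivity tables: `100 * detected / total`
#' rounded half-up to one decimal.
#'
#' @param detected,total Non-negative counts, `total > 0`.
#' @return Percent, one decimal.
#' @examples
#' sensitivity_percent(8, 9)    # 88.9
#' sensitivity_percent(15, 23)  # 65.2
#' @export
sensitivity_percent <- function(detected, total) {
  if (any(total <= 0)) abort("total must be > 0")
  round_half_up(100 * detected / total, 1)
}
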