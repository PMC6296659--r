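#' Count annotated exon targets overlapped by a call
#'
#' @param calls Calls tibble (`chrom`, `start`, `end`).
#' @param design Capture design with `gene`/`exon` annotation; each
#'   region is one exon target. Overlap of >= 1 bp counts.
#' @return Integer vector, one count per call.
#' @export
count_exons <- function(calls, design) {
  assert_columns(design, c("chrom", "start", "end"), "design")
  hits <- overlap_hits(calls, design)
  vapply(hits, length, integer(1))
}

# Expected VAF band for a copy-number state at a given site depth. Below
# depth 30 the band widens with binomial sampling noise, 2*sqrt(0.25/n).
vaf_band_width <- function(depth, band_half_width = 0.1) {
  pmax(band_half_width, ifelse(depth < 30, 2 * sqrt(0.25 / pmax(depth, 1)),
                               band_half_width))
}

vaf_in_band <- function(frac, cn, width) {
  if (cn <= 1) return(frac <= 0.1 | frac >= 0.9)
  if (cn == 2) return(abs(frac - 0.5) <= width)
  abs(frac - 1 / 3) <= width | abs(frac - 2 / 3) <= width
}

#' Allele-fraction consistency of a call with het SNP counts
#'
#' For every het-callable SNP (total depth >= 1) inside the call, checks
#' whether the alternate-read fraction lies in the band expected for the
#' call's copy number: near 0 or 1 for deletions (hemizygous or absent),
#' around 1/3 or 2/3 for a duplication, around 1/2 for diploid. Returns
#' the in-band fraction of sites, or `NA` when no SNPs overlap the call.
#'
#' @param call One-row data frame with `sample`, `chrom`, `start`, `end`,
#'   `cn`.
#' @param snps SNP tibble (`sample`, `chrom`, `pos` 1-based, `ref_count`,
#'   `alt_count`).
#' @param band_half_width Half-width of the dosage band at depth >= 30.
#' @return Fraction in `[0, 1]` or `NA_real_`.
#' @export
vaf_consistency <- function(call, snps, band_half_width = 0.1) {
  if (is.null(snps) || nrow(snps) == 0) return(NA_real_)
  hit <- snps$sample == call$sample[1] & snps$chrom == call$chrom[1] &
    snps$pos - 1 >= call$start[1] & snps$pos - 1 < call$end[1]
  sub <- snps[hit, ]
  depth <- sub$ref_count + sub$alt_count
  sub <- sub[depth >= 1, ]
  depth <- depth[depth >= 1]
  if (nrow(sub) == 0) return(NA_real_)
  frac <- sub$alt_count / depth
  width <- vaf_band_width(depth, band_half_width)
  mean(vaf_in_band(frac, call$cn[1], width))
}

#' Cohort recurrence of each call
#'
#' Number of *other* samples carrying a same-direction call with at least
#' `reciprocal` reciprocal overlap. Recurrent calls are characteristic of
#' polymorphic regions and are down-weighted at tier assignment.
#'
#' @param calls Calls tibble (`sample`, `chrom`, `start`, `end`, `cn`).
#' @param reciprocal Minimum reciprocal overlap (default 0.5).
#' @return Integer vector, one count per call.
#' @export
cohort_recurrence <- function(calls, reciprocal = 0.5) {
  n <- nrow(calls)
  if (n == 0) return(integer())
  dir <- cn_direction(calls$cn)
  vapply(seq_len(n), function(i) {
    cand <- which(calls$sample != calls$sample[i] &
                    calls$chrom == calls$chrom[i] & dir == dir[i])
    if (length(cand) == 0) return(0L)
    ro <- reciprocal_overlap(calls[i, ], calls[cand, ])
    length(unique(calls$sample[cand[ro >= reciprocal]]))
  }, integer(1))
}

#' Annotate CNV calls for prioritization
#'
#' Adds the adjudication metrics used at sign-out: call size, number of
#' overlapped exon targets, best Jaccard similarity to a same-direction
#' record in a ClinGen/ISCA-style classified database (plus that record's
#' classification), maximum population frequency among overlapping
#' same-direction DGV-style records, cohort recurrence, allele-fraction
#' consistency, and a priority tier from [assign_tier()].
#'
#' @param calls A `wescnv_calls` tibble.
#' @param design Capture design (for exon counts).
#' @param snps Optional SNP allele-count tibble.
#' @param isca Optional classified-database tibble (`chrom`, `start`,
#'   `end`, `classification`, `dosage_type` with values `"loss"`/
#'   `"gain"`).
#' @param dgv Optional population-database tibble (`chrom`, `start`,
#'   `end`, `frequency`, `dosage_type`).
#' @param reciprocal Reciprocal-overlap threshold for recurrence.
#' @param band_half_width VAF band half-width.
#' @param thresholds Tier thresholds from [tier_thresholds()].
#' @return The calls with columns `size_bp`, `n_exons`,
#'   `isca_best_similarity`, `isca_class`, `dgv_max_freq`, `recurrence`,
#'   `vaf_consistency`, `tier` appended. Re-annotating is idempotent.
#' @export
annotate_calls <- function(calls, design, snps = NULL, isca = NULL,
                           dgv = NULL, reciprocal = 0.5,
                           band_half_width = 0.1,
                           thresholds = tier_thresholds()) {
  ann_cols <- c("size_bp", "n_exons", "isca_best_similarity", "isca_class",
                "dgv_max_freq", "recurrence", "vaf_consistency", "tier")
  base <- calls[, setdiff(names(calls), ann_cols)]
  n <- nrow(base)
  out <- dplyr::mutate(base, size_bp = .data$end - .data$start)
  out$n_exons <- count_exons(base, design)
  out$recurrence <- cohort_recurrence(base, reciprocal = reciprocal)

  dirs <- cn_direction(base$cn)
  best_sim <- rep(0, n)
  best_class <- rep(NA_character_, n)
  if (!is.null(isca) && nrow(isca) > 0) {
    assert_columns(isca, c("chrom", "start", "end", "classification",
                           "dosage_type"), "isca table")
    for (i in seq_len(n)) {
      want <- if (dirs[i] == "del") "loss" else "gain"
      cand <- which(isca$chrom == base$chrom[i] & isca$dosage_type == want)
      if (length(cand) == 0) next
      sims <- jaccard_similarity(base[i, ], isca[cand, ])
      j <- which.max(sims)
      if (sims[j] > 0) {
        best_sim[i] <- sims[j]
        best_class[i] <- isca$classification[cand[j]]
      }
    }
  }
  out$isca_best_similarity <- best_sim
  out$isca_class <- best_class

  max_freq <- rep(NA_real_, n)
  if (!is.null(dgv) && nrow(dgv) > 0) {
    assert_columns(dgv, c("chrom", "start", "end", "frequency",
                          "dosage_type"), "dgv table")
    for (i in seq_len(n)) {
      want <- if (dirs[i] == "del") "loss" else "gain"
      cand <- which(dgv$chrom == base$chrom[i] & dgv$dosage_type == want)
      if (length(cand) == 0) next
      ov <- overlap_bp(base[i, ], dgv[cand, ])
      if (any(ov > 0)) max_freq[i] <- max(dgv$frequency[cand[ov > 0]])
    }
  }
  out$dgv_max_freq <- max_freq

  out$vaf_consistency <- vapply(seq_len(n), function(i) {
    vaf_consistency(out[i, ], snps, band_half_width = band_half_width)
  }, numeric(1))

  out$tier <- assign_tier(out, thresholds)
  tibble::new_tibble(out, class = "wescnv_calls")
}

#' Tier thresholds for call prioritization
#'
#' The defaults encode the filtering tiers used for sign-out review:
#' Bayes factor above 100 for high-priority review and above 20 for the
#' medium tier, a 100 kb size criterion, a minimum exon count, a Jaccard
#' similarity floor against classified pathogenic records, and a cap on
#' how many other cohort samples may share the call.
#'
#' @param bf_high,bf_medium Bayes-factor cutoffs.
#' @param size_bp Size criterion in bp.
#' @param min_exons Minimum overlapped exon targets for the high tier.
#' @param isca_similarity Jaccard floor for a pathogenic-record match.
#' @param recurrence_cap Maximum other-sample recurrence.
#' @return Named list of thresholds.
#' @export
tier_thresholds <- function(bf_high = 100, bf_medium = 20,
                            size_bp = 1e5, min_exons = 3,
                            isca_similarity = 0.5, recurrence_cap = 2) {
  list(bf_high = bf_high, bf_medium = bf_medium, size_bp = size_bp,
       min_exons = min_exons, isca_similarity = isca_similarity,
       recurrence_cap = recurrence_cap)
}

#' Assign priority tiers to annotated calls
#'
#' `high`: Bayes factor above `bf_high`, at least `min_exons` exons, not
#' recurrent beyond `recurrence_cap`, and either larger than `size_bp` or
#' matching a classified pathogenic record at Jaccard
#' `>= isca_similarity`. `medium`: Bayes factor above `bf_medium`, not
#' high, within the recurrence cap. Everything else is `low`.
#'
#' @param annotated Annotated calls (needs `bayes_factor`, `n_exons`,
#'   `size_bp`, `isca_best_similarity`, `isca_class`, `recurrence`).
#' @param thresholds From [tier_thresholds()].
#' @return Character vector of tiers.
#' @export
assign_tier <- function(annotated, thresholds = tier_thresholds()) {
  th <- thresholds
  patho <- !is.na(annotated$isca_class) &
    annotated$isca_class == "pathogenic" &
    annotated$isca_best_similarity >= th$isca_similarity
  high <- annotated$bayes_factor > th$bf_high &
    annotated$n_exons >= th$min_exons &
    annotated$recurrence <= th$recurrence_cap &
    (annotated$size_bp > th$size_bp | patho)
  medium <- !high & annotated$bayes_factor > th$bf_medium &
    annotated$recurrence <= th$recurrence_cap
  dplyr::case_when(high ~ "high", medium ~ "medium", TRUE ~ "low")
}
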