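#' Pipeline configuration
#'
#' Collects every tunable of the pipeline in one validated list so a run
#' is auditable from its configuration alone. Unknown keys are rejected;
#' each numeric field is checked against its documented range.
#'
#' @param window_bp Read-count window width, bp.
#' @param max_members Maximum reference-set members.
#' @param q Per-window probability of leaving the diploid HMM state.
#' @param L Expected CNV length in windows.
#' @param zero_ratio_threshold Observed-ratio cutoff for relabeling a
#'   deletion call CN 0.
#' @param grubbs_alpha Grubbs significance level.
#' @param grubbs_iterative Iterative Grubbs re-testing.
#' @param mosaic_min Minimum mosaic fraction for an aneuploidy finding.
#' @param tier Tier thresholds, see [tier_thresholds()].
#' @param min_overlap_bp Concordance matching overlap, bp.
#' @param reciprocal Reciprocal-overlap threshold (recurrence, repeat
#'   flags).
#' @param min_depth Minimum cohort-median depth for "adequately covered".
#' @param seed Default seed for simulation subcommands.
#' @param ... Rejected; catches unknown keys.
#' @return A `wescnv_config` list.
#' @export
wescnv_config <- function(window_bp = 100, max_members = 10, q = 1e-4,
                          L = 50, zero_ratio_threshold = 0.15,
                          grubbs_alpha = 0.05, grubbs_iterative = TRUE,
                          mosaic_min = 0.2, tier = tier_thresholds(),
                          min_overlap_bp = 1, reciprocal = 0.5,
                          min_depth = 10, seed = 1, ...) {
  extra <- list(...)
  if (length(extra) > 0) {
    abort(paste0("unknown config key(s): ",
                 paste(names(extra), collapse = ", ")))
  }
  stopifnot(is_count(window_bp), is_count(max_members),
            q > 0, q < 0.5, L >= 1,
            zero_ratio_threshold > 0, zero_ratio_threshold < 1,
            grubbs_alpha > 0, grubbs_alpha < 1,
            is.logical(grubbs_iterative),
            mosaic_min >= 0, mosaic_min <= 1,
            min_overlap_bp >= 1, reciprocal > 0, reciprocal <= 1,
            min_depth >= 0)
  structure(
    list(window_bp = window_bp, max_members = max_members, q = q, L = L,
         zero_ratio_threshold = zero_ratio_threshold,
         grubbs_alpha = grubbs_alpha, grubbs_iterative = grubbs_iterative,
         mosaic_min = mosaic_min, tier = tier,
         min_overlap_bp = min_overlap_bp, reciprocal = reciprocal,
         min_depth = min_depth, seed = seed),
    class = "wescnv_config"
  )
}

#' @export
print.wescnv_config <- function(x, ...) {
  cat("<wescnv_config>\n")
  flat <- c(x[setdiff(names(x), "tier")],
            setNames(x$tier, paste0("tier.", names(x$tier))))
  for (k in names(flat)) cat(sprintf("  %-22s %s\n", k, flat[[k]]))
  invisible(x)
}

#' Load a configuration from a YAML file with overrides
#'
#' @param path YAML file path, or `NULL` for defaults.
#' @param overrides Named list applied on top of the file.
#' @return A validated `wescnv_config`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("the yaml package is required to read config files")
    }
    vals <- yaml::read_yaml(path)
  }
  vals[names(overrides)] <- overrides
  if (!is.null(vals$tier)) vals$tier <- do.call(tier_thresholds, vals$tier)
  do.call(wescnv_config, vals)
}
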