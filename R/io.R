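#' Read and write interval files
#'
#' BED files are 0-based half-open — identical to the in-memory
#' convention, so no conversion happens. All TSV call/truth/database
#' formats are 1-based inclusive on disk (the convention of clinical
#' reports): reading subtracts 1 from `start`, writing adds 1, and the
#' conversion round-trips losslessly. Malformed rows fail with the
#' offending line number.
#'
#' @param path File path.
#' @param design,calls,counts,snps Objects to write.
#' @name wescnv_io
NULL

read_tsv_quiet <- function(path, col_types = NULL) {
  readr::read_tsv(path, col_types = col_types, progress = FALSE,
                  show_col_types = FALSE)
}

check_disk_coords <- function(df, path, one_based = TRUE) {
  bad <- if (one_based) which(df$start > df$end) else which(df$start >= df$end)
  if (length(bad) > 0) {
    abort(sprintf("%s: start > end at data line %d", path, bad[1]))
  }
  if (any(df$start < 0)) {
    abort(sprintf("%s: negative coordinate at data line %d", path,
                  which(df$start < 0)[1]))
  }
  invisible(df)
}

#' @rdname wescnv_io
#' @export
read_design_bed <- function(path) {
  df <- readr::read_tsv(path,
                        col_names = c("chrom", "start", "end", "name"),
                        col_types = "ciic", progress = FALSE)
  check_disk_coords(df, path, one_based = FALSE)
  parts <- strsplit(df$name, "|", fixed = TRUE)
  regions <- tibble::tibble(
    chrom = df$chrom, start = df$start, end = df$end,
    gene = vapply(parts, `[`, character(1), 1),
    exon = as.integer(vapply(parts, `[`, character(1), 2))
  )
  lengths <- regions |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(len = max(.data$end) + 1000) |>
    tibble::deframe()
  new_capture_design(regions, lengths[unique(regions$chrom)])
}

#' @rdname wescnv_io
#' @export
write_design_bed <- function(design, path) {
  readr::write_tsv(
    tibble::tibble(chrom = design$chrom, start = design$start,
                   end = design$end,
                   name = paste0(design$gene, "|", design$exon)),
    path, col_names = FALSE)
  invisible(path)
}

#' @rdname wescnv_io
#' @export
read_calls_tsv <- function(path) {
  df <- read_tsv_quiet(path)
  assert_columns(df, c("sample", "chrom", "start", "end"), path)
  check_disk_coords(df, path, one_based = TRUE)
  df$start <- df$start - 1
  df
}

#' @rdname wescnv_io
#' @export
write_calls_tsv <- function(calls, path) {
  out <- as.data.frame(calls)
  out$start <- out$start + 1
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname wescnv_io
#' @export
read_counts_tsv <- function(path) {
  df <- read_tsv_quiet(path)
  assert_columns(df, c("chrom", "start", "end", "window_id"), path)
  check_disk_coords(df, path, one_based = TRUE)
  if (anyDuplicated(df$window_id)) {
    abort(sprintf("%s: duplicate window id at data line %d", path,
                  anyDuplicated(df$window_id)))
  }
  df$start <- df$start - 1
  df
}

#' @rdname wescnv_io
#' @export
write_counts_tsv <- function(counts, path) {
  out <- as.data.frame(counts)
  out$start <- out$start + 1
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname wescnv_io
#' @export
read_snp_tsv <- function(path) {
  df <- read_tsv_quiet(path)
  assert_columns(df, c("sample", "chrom", "pos", "ref_count", "alt_count"),
                 path)
  if (any(df$ref_count < 0 | df$alt_count < 0)) {
    abort(sprintf("%s: negative count at data line %d", path,
                  which(df$ref_count < 0 | df$alt_count < 0)[1]))
  }
  df
}

#' @rdname wescnv_io
#' @export
write_snp_tsv <- function(snps, path) {
  readr::write_tsv(as.data.frame(snps), path)
  invisible(path)
}

#' @rdname wescnv_io
#' @export
read_database_tsv <- function(path) {
  df <- read_tsv_quiet(path)
  assert_columns(df, c("chrom", "start", "end", "classification",
                       "dosage_type"), path)
  check_disk_coords(df, path, one_based = TRUE)
  ok_class <- df$classification %in% c("pathogenic", "benign", "unknown")
  if (!all(ok_class)) {
    abort(sprintf("%s: unknown classification at data line %d", path,
                  which(!ok_class)[1]))
  }
  if ("frequency" %in% names(df) &&
      any(!is.na(df$frequency) & (df$frequency < 0 | df$frequency > 1))) {
    abort(sprintf("%s: frequency outside [0,1]", path))
  }
  df$start <- df$start - 1
  df
}
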