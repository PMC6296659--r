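#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an emission-parameter fit
#'
#' @param x A `wescnv_emission`.
#' @param ... Unused.
#' @return Tibble with one row per window: `window`, `phi`.
#' @export
tidy.wescnv_emission <- function(x, ...) {
  tibble::tibble(window = seq_along(x$phi), phi = x$phi)
}

#' @rdname tidy.wescnv_emission
#' @export
glance.wescnv_emission <- function(x, ...) {
  tibble::tibble(theta = x$theta, depth_ratio = x$depth_ratio,
                 n_windows = x$n_windows)
}

#' Tidy a reference-set selection
#'
#' @param x A `wescnv_reference`.
#' @param ... Unused.
#' @return Per-candidate tibble: `sample`, `correlation`, `member`.
#' @export
tidy.wescnv_reference <- function(x, ...) {
  dplyr::mutate(x$scores, member = .data$sample %in% x$members) |>
    dplyr::arrange(dplyr::desc(.data$correlation))
}

#' @rdname tidy.wescnv_reference
#' @export
glance.wescnv_reference <- function(x, ...) {
  tibble::tibble(test = x$test, n_members = length(x$members),
                 total_reference_reads = sum(x$r))
}

#' Summarise a call set
#'
#' @param x A `wescnv_calls` tibble.
#' @param ... Unused.
#' @return One-row tibble: call counts by direction and Bayes-factor
#'   tiers.
#' @export
glance.wescnv_calls <- function(x, ...) {
  tibble::tibble(
    n_calls = nrow(x),
    n_del = sum(x$cn < 2),
    n_dup = sum(x$cn > 2),
    n_bf20 = sum(x$bayes_factor > 20),
    n_bf100 = sum(x$bayes_factor > 100),
    median_size_bp = if (nrow(x)) median(x$end - x$start) else NA_real_
  )
}

#' Summarise an aneuploidy scan
#'
#' @param x A `wescnv_aneuploidy` tibble.
#' @param ... Unused.
#' @return One-row tibble with finding counts and the karyotype-style
#'   summary string.
#' @export
glance.wescnv_aneuploidy <- function(x, ...) {
  tibble::tibble(
    n_tested = nrow(x),
    n_outliers = sum(x$outlier, na.rm = TRUE),
    n_findings = sum(x$is_aneuploidy, na.rm = TRUE),
    findings = paste(karyotype_summary(x), collapse = "; ")
  )
}

#' Plot window depth ratios with call tracks for one sample
#'
#' Shows the per-window observed/expected-diploid depth ratio along each
#' chromosome with called segments overlaid, the visual check used when
#' reviewing a CNV call.
#'
#' @param counts Wide counts tibble.
#' @param test Test sample id.
#' @param reference A `wescnv_reference` for `test`.
#' @param calls Optional `wescnv_calls` for `test`.
#' @param params Optional `wescnv_emission`.
#' @return A ggplot object.
#' @export
plot_depth_ratio <- function(counts, test, reference, calls = NULL,
                             params = NULL) {
  mat <- counts_matrix(counts)
  y <- mat[, test]
  r <- reference$r
  if (is.null(params)) params <- fit_emission_params(y, r, counts$chrom)
  n <- y + r
  df <- tibble::tibble(
    chrom = factor(counts$chrom, levels = unique(counts$chrom)),
    pos = (counts$start + counts$end) / 2,
    ratio = ifelse(n > 0, y / (params$phi * n), NA_real_)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$ratio)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::geom_hline(yintercept = c(0.5, 1, 1.5), linetype = "dotted") +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "observed / expected diploid",
                  title = paste("Depth ratio:", test)) +
    ggplot2::theme_minimal()
  if (!is.null(calls) && nrow(calls) > 0) {
    seg <- dplyr::filter(calls, .data$sample == test) |>
      dplyr::mutate(chrom = factor(.data$chrom, levels = levels(df$chrom)))
    if (nrow(seg) > 0) {
      p <- p + ggplot2::geom_segment(
        data = seg,
        ggplot2::aes(x = .data$start, xend = .data$end,
                     y = .data$cn / 2, yend = .data$cn / 2),
        color = "red", linewidth = 1.2, inherit.aes = FALSE)
    }
  }
  p
}

#' @export
autoplot.wescnv_aneuploidy <- function(object, ...) {
  df <- dplyr::filter(object, !is.na(.data$ratio)) |>
    dplyr::mutate(chrom = factor(.data$chrom, levels = unique(.data$chrom)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$chrom, y = .data$ratio)) +
    ggplot2::geom_jitter(ggplot2::aes(color = .data$is_aneuploidy),
                         width = 0.15, height = 0, size = 1.5) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey40",
                                           `TRUE` = "red"),
                                name = "aneuploidy") +
    ggplot2::labs(x = NULL, y = "coverage ratio") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @export
autoplot.wescnv_calls <- function(object, ...) {
  if (nrow(object) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "No CNV calls"))
  }
  df <- dplyr::mutate(object,
                      size_kb = (.data$end - .data$start) / 1000,
                      direction = cn_direction(.data$cn))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size_kb,
                                   y = .data$bayes_factor,
                                   color = .data$direction)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::geom_hline(yintercept = c(20, 100), linetype = "dashed") +
    ggplot2::labs(x = "call size (kb)", y = "Bayes factor (log10 LR)") +
    ggplot2::theme_minimal()
}
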