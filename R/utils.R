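#' @importFrom rlang .data abort %||%
#' @importFrom stats rnorm rpois rnbinom rbinom runif rexp cor dbinom
#'   median qt rlnorm setNames sd
#' @importFrom utils head tail
NULL

# Run code with a fixed RNG state, restoring the caller's state afterwards.
# All stochastic operations in the package funnel through this so no call
# perturbs global RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministically derive a child seed from a parent seed and a salt, so
# independent stages of a simulation consume independent streams.
derive_seed <- function(seed, salt) {
  as.integer((as.double(seed) * 7919 + salt * 104729) %% 2147483587L) + 1L
}

# Round half away from zero (R's round() is banker's rounding).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
}

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(paste0(what, " is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Copy-number direction: deletion (cn < 2), duplication (cn > 2).
cn_direction <- function(cn) {
  dplyr::case_when(cn < 2 ~ "del", cn > 2 ~ "dup", TRUE ~ "neutral")
}
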