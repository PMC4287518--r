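#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# row-wise means/variances for a features x samples matrix, NA-tolerant
row_means <- function(x) rowMeans(x, na.rm = TRUE)

row_vars <- function(x) {
  n <- rowSums(!is.na(x))
  mu <- rowMeans(x, na.rm = TRUE)
  ss <- rowSums(x^2, na.rm = TRUE) - n * mu^2
  ss / pmax(n - 1, 1)
}

row_sds <- function(x) sqrt(row_vars(x))

# average-rank transform of each row of a matrix
rank_rows <- function(x) {
  t(apply(x, 1, rank, ties.method = "average", na.last = "keep"))
}

# z-score a vector; constant input -> zeros
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# signed normal quantile of a two-sided p, carrying `sign`
p_to_z <- function(p, sign) {
  z <- -stats::qnorm(pmax(p, .Machine$double.xmin) / 2)
  z <- pmin(z, 38.4)  # qnorm underflow guard
  z * sign
}

stop_if_not_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    abort(sprintf("%s is missing required column(s): %s", what,
                  paste(miss, collapse = ", ")))
  }
}
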