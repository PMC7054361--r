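# Effect sizes reported alongside the delegated standard group tests.

#' Cohen's d for two independent groups
#'
#' `d = (mean(x) - mean(y)) / s` with `s` the pooled standard deviation
#' (n - 1 denominators) by default, or the second group's sd when
#' `pooled = FALSE`.
#'
#' @param x,y Numeric observations for the two groups (each of size >= 2).
#' @param pooled Use the pooled sd (default) or group `y`'s sd.
#' @return Cohen's d (antisymmetric under swapping the groups).
#' @export
cohens_d <- function(x, y, pooled = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    stop("both groups need at least 2 observations", call. = FALSE)
  }
  s <- if (pooled) {
    sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
           (length(x) + length(y) - 2))
  } else {
    sd(y)
  }
  if (s == 0) stop("zero standard deviation; d is undefined", call. = FALSE)
  (mean(x) - mean(y)) / s
}

#' Rank-biserial correlation for a Mann-Whitney comparison
#'
#' The dominance statistic `(#\{x > y\} - #\{x < y\}) / (n_x * n_y)` over all
#' cross-group pairs, computed from midranks so ties split evenly.
#' Equivalently `2 * U_x / (n_x * n_y) - 1` with `U_x` the Mann-Whitney
#' statistic counting pairs where `x` exceeds `y`. Ranges over `[-1, 1]`;
#' +1 means complete separation with every `x` above every `y`.
#'
#' @param x,y Numeric observations for the two groups (non-empty).
#' @return Rank-biserial r.
#' @export
rank_biserial_r <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  nx <- length(x); ny <- length(y)
  r_all <- rank(c(x, y))
  u_x <- sum(r_all[seq_len(nx)]) - nx * (nx + 1) / 2
  2 * u_x / (nx * ny) - 1
}

#' Partial eta squared from ANOVA sums of squares
#'
#' `ss_effect / (ss_effect + ss_error)`. The sums of squares come from
#' whatever ANOVA routine produced the test; this function owns only the
#' effect-size arithmetic.
#'
#' @param ss_effect,ss_error Non-negative sums of squares, not both zero.
#' @return Partial eta squared in `[0, 1]`.
#' @export
partial_eta_squared <- function(ss_effect, ss_error) {
  if (any(ss_effect < 0) || any(ss_error < 0)) {
    stop("sums of squares must be non-negative", call. = FALSE)
  }
  if (any(ss_effect + ss_error == 0)) {
    stop("ss_effect and ss_error cannot both be zero", call. = FALSE)
  }
  ss_effect / (ss_effect + ss_error)
}
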