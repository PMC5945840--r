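# DFA/DCCA engine. The profile of a series is its centered cumulative sum;
# it is split into floor(N/n) windows of length n from the left and the same
# number from the right (so no tail is discarded when n does not divide N),
# a polynomial trend is fitted in each window, and squared residuals (or
# residual cross-products for a pair of series) are averaged: first within a
# window with divisor n, then over all 2*floor(N/n) windows.

#' Integrated profile of a time series
#'
#' Cumulative sum of the mean-centered series,
#' \eqn{Z_t = \sum_{i \le t} (z_i - \bar z)}. The profile is the object that
#' is windowed and detrended by all fluctuation functions; its last element
#' is zero up to rounding.
#'
#' @param x Numeric series with finite values.
#' @return Numeric vector of the same length.
#' @examples
#' compute_profile(c(1, 2, 3))  # -1 -1 0
#' @export
compute_profile <- function(x) {
  check_series(x)
  cumsum(x - mean(x))
}

#' Two-sided segmentation of a series of length N at scale n
#'
#' Returns the `2 * floor(N/n)` windows used by the fluctuation functions:
#' `floor(N/n)` windows of length `n` starting from the first observation,
#' and the same number starting from the opposite end, so that no part of
#' the series is disregarded when `n` does not divide `N`. Windows are
#' returned in that order and may overlap.
#'
#' @param N Series length.
#' @param n Scale (window length), `n <= N`.
#' @return Integer matrix with columns `start` and `end` (1-based, inclusive).
#' @examples
#' segment_bounds(10, 4)
#' @export
segment_bounds <- function(N, n) {
  N <- as.integer(N); n <- as.integer(n)
  if (is.na(n) || n < 1L) stop_param("scale n must be >= 1")
  if (n > N) stop_param("scale n = %d exceeds series length N = %d", n, N)
  starts <- segment_starts(N, n)
  cbind(start = starts + 1L, end = starts + n)
}

# 0-based window offsets, forward then backward.
segment_starts <- function(N, n) {
  n_seg <- N %/% n
  c((seq_len(n_seg) - 1L) * n, N - seq_len(n_seg) * n)
}

# Orthonormal basis of polynomials of degree <= order on abscissa 1..n.
# Detrending a window is projection off this basis, which is linear -- the
# property the residual-fluctuation identity in dfa_fit() relies on.
detrend_basis <- function(n, order) {
  qr.Q(qr(outer(seq_len(n), 0:order, `^`)))
}

# Matrix of scale-n fluctuation values for all column pairs of `profiles`
# (an N x p matrix of profiles): entry (i, j) is F^2_{ij}(n), the average
# over the 2*floor(N/n) windows of the mean within-window product of the two
# detrended profiles. Diagonal entries are DFA variances.
fluct_matrix <- function(profiles, n, order) {
  N <- nrow(profiles)
  n <- as.integer(n)
  if (is.na(n) || n < order + 2L) {
    stop_param("scale n = %s too small for detrend order %d (need n >= %d)",
               format(n), order, order + 2L)
  }
  if (n > N) stop_param("scale n = %d exceeds series length N = %d", n, N)
  starts <- segment_starts(N, n)
  idx <- rep(starts, each = n) + seq_len(n)
  Q <- detrend_basis(n, order)
  p <- ncol(profiles)
  D <- matrix(0, length(idx), p)
  for (j in seq_len(p)) {
    M <- matrix(profiles[idx, j], nrow = n)
    D[, j] <- M - Q %*% crossprod(Q, M)
  }
  crossprod(D) / length(idx)
}

check_order <- function(order) {
  order <- as.integer(order)
  if (is.na(order) || order < 0L) stop_param("detrend order must be >= 0")
  order
}

check_grid <- function(grid, N, order) {
  if (!is.numeric(grid) || length(grid) < 1L) {
    stop_param("scale grid must be a non-empty numeric vector")
  }
  grid <- as.integer(round(grid))
  if (is.unsorted(grid, strictly = TRUE)) grid <- sort(unique(grid))
  if (grid[1L] < order + 2L) {
    stop_param("smallest scale %d below minimum %d for detrend order %d",
               grid[1L], order + 2L, order)
  }
  if (grid[length(grid)] > N) {
    stop_param("largest scale %d exceeds series length %d",
               grid[length(grid)], N)
  }
  grid
}

#' Logarithmically spaced integer scale grid
#'
#' `n_scales` log-spaced values between `n_min` and `n_max`, rounded to
#' integers with duplicates removed. This is the default grid on which all
#' scale-dependent quantities are evaluated (10 to min(1000, N/4) with 30
#' points when derived from a series length).
#'
#' @param n_min,n_max Smallest and largest scale (inclusive).
#' @param n_scales Number of grid points before rounding (default 30).
#' @return Strictly increasing integer vector.
#' @examples
#' scale_grid(10, 1000)
#' @export
scale_grid <- function(n_min, n_max, n_scales = 30L) {
  if (n_min < 2) stop_param("n_min must be >= 2")
  if (n_max < n_min) stop_param("n_max must be >= n_min")
  if (n_scales < 1) stop_param("n_scales must be >= 1")
  sort(unique(as.integer(round(
    exp(seq(log(n_min), log(n_max), length.out = n_scales))))))
}

default_grid <- function(N, n_min = 10L, n_max = 1000L, n_scales = 30L) {
  hi <- min(n_max, N %/% 4L)
  if (hi < n_min) {
    stop_param("series too short (N = %d) for scales starting at %d", N, n_min)
  }
  scale_grid(n_min, hi, n_scales)
}

#' Scale-dependent DFA variance function
#'
#' For each scale n of the grid, fits a polynomial of the stated order to
#' the series profile within each of the `2*floor(N/n)` two-sided windows,
#' averages the squared residuals within windows (divisor n), then averages
#' over windows. The result \eqn{F^2(n)} is the DFA-based variance of the
#' series at scale n; its log-log slope against n estimates the Hurst
#' exponent.
#'
#' @param x Numeric series.
#' @param grid Integer vector of scales; default 30 log-spaced scales in
#'   `[10, min(1000, N/4)]`.
#' @param order Polynomial detrend order (default 2).
#' @return Object of class `"fluctuation_set"`: a list with `scale`, `f2`,
#'   `kind = "variance"` and `order`.
#' @seealso [dcca_covariance()], [dfa_fit()]
#' @export
dfa_variance <- function(x, grid = NULL, order = 2L) {
  check_series(x, min_len = 4L)
  order <- check_order(order)
  if (is.null(grid)) grid <- default_grid(length(x))
  grid <- check_grid(grid, length(x), order)
  prof <- matrix(compute_profile(x), ncol = 1L)
  f2 <- vapply(grid, function(n) fluct_matrix(prof, n, order)[1L, 1L],
               numeric(1))
  structure(list(scale = grid, f2 = f2, kind = "variance", order = order),
            class = "fluctuation_set")
}

#' Scale-dependent DCCA covariance function
#'
#' Bivariate counterpart of [dfa_variance()]: each series' profile is
#' detrended independently in the same two-sided windows and the mean
#' within-window product of the two detrended profiles is averaged over
#' windows. Unlike the variance, \eqn{F^2_{ab}(n)} may be negative. With
#' `a` identical to `b` it reduces exactly to the DFA variance.
#'
#' @inheritParams dfa_variance
#' @param a,b Numeric series of equal length.
#' @return Object of class `"fluctuation_set"` with `kind = "covariance"`.
#' @export
dcca_covariance <- function(a, b, grid = NULL, order = 2L) {
  check_series(a, min_len = 4L)
  check_series(b, min_len = 4L)
  check_equal_length(a, b)
  order <- check_order(order)
  if (is.null(grid)) grid <- default_grid(length(a))
  grid <- check_grid(grid, length(a), order)
  prof <- cbind(compute_profile(a), compute_profile(b))
  f2 <- vapply(grid, function(n) fluct_matrix(prof, n, order)[1L, 2L],
               numeric(1))
  structure(list(scale = grid, f2 = f2, kind = "covariance", order = order),
            class = "fluctuation_set")
}

#' @export
print.fluctuation_set <- function(x, ...) {
  cat(sprintf("Scale-dependent %s function (order-%d detrending, %d scales)\n",
              x$kind, x$order, length(x$scale)))
  print(data.frame(scale = x$scale, f2 = x$f2), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.fluctuation_set <- function(x, ...) {
  data.frame(scale = x$scale, f2 = x$f2)
}
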