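# Correlation-type statistics: the classical partial Pearson coefficient
# with its t-statistic, and the scale-dependent DCCA / partial DCCA
# coefficients built from the fluctuation engine.

#' Partial Pearson correlation with t-statistic
#'
#' Correlation between `a` and `b` eliminating the linear effect of `c`:
#' \deqn{r_{12,3} = \frac{r_{12} - r_{13} r_{23}}
#'   {\sqrt{(1 - r_{13}^2)(1 - r_{23}^2)}}}
#' with the test statistic \eqn{t = r_{12,3}\sqrt{(N-3)/(1 - r_{12,3}^2)}}
#' on `N - 3` degrees of freedom. `t` is infinite (flagged) when
#' \eqn{|r_{12,3}| = 1}.
#'
#' @param a,b,c Equal-length numeric series (`N >= 4`), none constant.
#' @return Object of class `"partial_correlation"`: list with `r`, `t`,
#'   `dof`.
#' @export
partial_pearson <- function(a, b, c) {
  check_series(a, min_len = 4L)
  check_series(b, min_len = 4L)
  check_series(c, min_len = 4L)
  N <- check_equal_length(a, b, c)
  if (stats::sd(a) == 0 || stats::sd(b) == 0 || stats::sd(c) == 0) {
    stop_degenerate("constant series have no defined correlation")
  }
  r12 <- stats::cor(a, b); r13 <- stats::cor(a, c); r23 <- stats::cor(b, c)
  if (abs(r13) >= 1 || abs(r23) >= 1) {
    stop_degenerate("conditioning series is perfectly correlated with an input")
  }
  r <- (r12 - r13 * r23) / sqrt((1 - r13^2) * (1 - r23^2))
  # rounding can push |r| epsilon past 1 for near-collinear inputs
  if (abs(r) > 1 && abs(r) < 1 + 1e-12) r <- sign(r)
  t <- if (abs(r) < 1) r * sqrt((N - 3) / (1 - r^2)) else sign(r) * Inf
  structure(list(r = r, t = t, dof = N - 3L), class = "partial_correlation")
}

#' @export
print.partial_correlation <- function(x, ...) {
  cat(sprintf("Partial correlation r = %.4f, t = %.4f on %d df\n",
              x$r, x$t, x$dof))
  invisible(x)
}

#' DCCA cross-correlation coefficient at one scale
#'
#' \deqn{\rho_{DCCA}(n) = F^2_{ab}(n) / \sqrt{F^2_a(n) F^2_b(n)}}, the
#' scale-dependent correlation of two nonstationary series: the DCCA
#' covariance normalized by the two DFA standard fluctuations. The value is
#' reported as computed (never clipped); a violation of \eqn{|\rho| \le 1}
#' beyond 1e-9 raises an internal-consistency error.
#'
#' @param a,b Equal-length numeric series.
#' @param n Scale (window length).
#' @param order Polynomial detrend order (default 2).
#' @return Scalar correlation in `[-1, 1]`.
#' @export
rho_dcca <- function(a, b, n, order = 2L) {
  check_series(a, min_len = 4L)
  check_series(b, min_len = 4L)
  check_equal_length(a, b)
  order <- check_order(order)
  F <- fluct_matrix(cbind(compute_profile(a), compute_profile(b)),
                    n, order)
  if (F[1L, 1L] <= 0 || F[2L, 2L] <= 0) {
    stop_degenerate("zero DFA variance at scale %d: coefficient undefined", n)
  }
  rho <- F[1L, 2L] / sqrt(F[1L, 1L] * F[2L, 2L])
  if (abs(rho) > 1 + 1e-9) {
    stop("internal consistency failure: |rho_DCCA| = ", format(abs(rho)),
         " exceeds 1")
  }
  rho
}

#' Matrix of pairwise DCCA coefficients at one scale
#'
#' Symmetric m-by-m matrix of \eqn{\rho_{DCCA}(n)} values for a list of
#' series, with the diagonal set to exactly 1 (avoiding rounding-induced
#' non-invertibility when the matrix is inverted for partial coefficients).
#'
#' @param series_list List of equal-length numeric series (m >= 2).
#' @inheritParams rho_dcca
#' @return Numeric matrix with dimnames taken from `series_list` names.
#' @export
dcca_matrix <- function(series_list, n, order = 2L) {
  if (!is.list(series_list) || length(series_list) < 2L) {
    stop_input("series_list must be a list of at least two series")
  }
  for (s in series_list) check_series(s, "series_list element", min_len = 4L)
  do.call(check_equal_length, series_list)
  order <- check_order(order)
  profs <- vapply(series_list, compute_profile,
                  numeric(length(series_list[[1L]])))
  F <- fluct_matrix(profs, n, order)
  v <- diag(F)
  if (any(v <= 0)) {
    stop_degenerate("zero DFA variance at scale %d: matrix undefined", n)
  }
  R <- F / sqrt(outer(v, v))
  if (any(abs(R) > 1 + 1e-9)) {
    stop("internal consistency failure: |rho_DCCA| exceeds 1 at scale ", n)
  }
  diag(R) <- 1
  dimnames(R) <- list(names(series_list), names(series_list))
  R
}

#' Partial DCCA coefficient at one scale
#'
#' Scale-dependent partial correlation between series `i` and `j`,
#' eliminating the influence of all other series in the list: with `C` the
#' inverse of the pairwise \eqn{\rho_{DCCA}(n)} matrix,
#' \deqn{\rho_{PDCCA}(i, j; n) = -C_{ij} / \sqrt{C_{ii} C_{jj}}.}
#' For two series this reduces exactly to \eqn{\rho_{DCCA}(n)}; the
#' diagonal (`i == j`) is defined as 1.
#'
#' @inheritParams dcca_matrix
#' @param i,j Indices of the pair of interest in `series_list`.
#' @return Scalar partial correlation.
#' @export
rho_pdcca <- function(series_list, i, j, n, order = 2L) {
  R <- dcca_matrix(series_list, n, order)
  m <- nrow(R)
  i <- as.integer(i); j <- as.integer(j)
  if (is.na(i) || is.na(j) || i < 1L || j < 1L || i > m || j > m) {
    stop_input("pair indices must lie in 1..%d", m)
  }
  if (i == j) return(1)
  if (rcond(R) < 1e-12) {
    stop_degenerate("DCCA correlation matrix is near-singular at scale %d", n)
  }
  C <- solve(R)
  -C[i, j] / sqrt(C[i, i] * C[j, j])
}
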