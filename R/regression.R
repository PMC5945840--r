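# Bivariate regression Y = b0 + b1*X1 + b2*X2 + e in two forms: the
# classical OLS fit expressed through (co)variances of the centered series,
# and its scale-dependent counterpart in which every (co)variance is
# replaced by the DFA variance / DCCA covariance at scale n. The second form
# is the core estimator of the package.

#' Classical bivariate OLS fit with evaluation indices
#'
#' Ordinary least squares for `y = b0 + b1*x1 + b2*x2 + e`, written in the
#' variance/covariance closed form: with centered series,
#' \deqn{\hat\beta_1 = (S_{x_1 y} S_{x_2 x_2} - S_{x_2 y} S_{x_1 x_2}) /
#'       (S_{x_1 x_1} S_{x_2 x_2} - S_{x_1 x_2}^2)}
#' and symmetrically for \eqn{\hat\beta_2}. Coefficient variances use the
#' residual sum of squares with the `N - 3` divisor. Also returns the
#' determination coefficient \eqn{R^2}, the standardized (beta) coefficients
#' \eqn{\beta_j^* = \hat\beta_j \sqrt{S_{x_j x_j} / S_{yy}}} and the average
#' elasticities \eqn{\eta_j = \hat\beta_j \bar X_j / \bar Y} (undefined and
#' flagged when `mean(y)` is zero).
#'
#' @param y Response series.
#' @param x1,x2 Regressor series, equal length with `y`, not collinear.
#' @return Object of class `"ols_fit"`: list with `beta0`, `beta1`, `beta2`,
#'   `var1`, `var2`, `residuals` (zero mean), `r_squared`, `beta_star1`,
#'   `beta_star2`, `eta1`, `eta2`, `eta_defined`, `N`.
#' @examples
#' x1 <- rnorm(100); x2 <- rnorm(100)
#' fit <- ols_fit(1 + x1 + 2 * x2 + rnorm(100), x1, x2)
#' @export
ols_fit <- function(y, x1, x2) {
  check_series(y, min_len = 4L)
  check_series(x1, min_len = 4L)
  check_series(x2, min_len = 4L)
  N <- check_equal_length(y, x1, x2)
  cy <- y - mean(y); c1 <- x1 - mean(x1); c2 <- x2 - mean(x2)
  s11 <- sum(c1 * c1); s22 <- sum(c2 * c2); s12 <- sum(c1 * c2)
  s1y <- sum(c1 * cy); s2y <- sum(c2 * cy); syy <- sum(cy * cy)
  den <- s11 * s22 - s12 * s12
  if (!is.finite(den) || den <= 1e-12 * s11 * s22) {
    stop_degenerate("regressors are collinear (normal system singular)")
  }
  beta1 <- (s1y * s22 - s2y * s12) / den
  beta2 <- (s2y * s11 - s1y * s12) / den
  beta0 <- mean(y) - beta1 * mean(x1) - beta2 * mean(x2)
  e <- y - beta1 * x1 - beta2 * x2
  e <- e - mean(e)
  sse <- sum(e * e)
  sigma2 <- sse / (N - 3)
  eta_defined <- mean(y) != 0
  structure(list(
    beta0 = beta0, beta1 = beta1, beta2 = beta2,
    var1 = s22 * sigma2 / den, var2 = s11 * sigma2 / den,
    residuals = e,
    r_squared = 1 - sse / syy,
    beta_star1 = beta1 * sqrt(s11 / syy),
    beta_star2 = beta2 * sqrt(s22 / syy),
    eta1 = if (eta_defined) beta1 * mean(x1) / mean(y) else NA_real_,
    eta2 = if (eta_defined) beta2 * mean(x2) / mean(y) else NA_real_,
    eta_defined = eta_defined,
    N = N), class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("Bivariate OLS fit (N = %d)\n", x$N))
  cat(sprintf("  beta0 = %.6g, beta1 = %.6g (var %.3g), beta2 = %.6g (var %.3g)\n",
              x$beta0, x$beta1, x$var1, x$beta2, x$var2))
  cat(sprintf("  R^2 = %.4f, beta* = (%.4g, %.4g), eta = (%.4g, %.4g)\n",
              x$r_squared, x$beta_star1, x$beta_star2, x$eta1, x$eta2))
  invisible(x)
}

#' Scale-dependent DFA-based bivariate regression
#'
#' At every scale n of the grid the six fluctuation functions
#' \eqn{F^2_{X_1}, F^2_{X_2}, F^2_Y, F^2_{X_1 X_2}, F^2_{X_1 Y}, F^2_{X_2 Y}}
#' are computed once and combined exactly as the OLS closed form combines
#' (co)variances:
#' \deqn{\hat\beta_1(n) = \frac{F^2_{X_1 Y}(n) F^2_{X_2}(n) -
#'   F^2_{X_2 Y}(n) F^2_{X_1 X_2}(n)}{F^2_{X_1}(n) F^2_{X_2}(n) -
#'   [F^2_{X_1 X_2}(n)]^2}}
#' and symmetrically for \eqn{\hat\beta_2(n)}. The scale-dependent residual
#' series \eqn{\hat e_t(n) = Y_t - \hat\beta_1(n) X_{1t} - \hat\beta_2(n)
#' X_{2t}}, re-centered to zero mean, is rebuilt for each n and its DFA
#' variance evaluated at that same scale gives \eqn{F^2_\varepsilon(n)},
#' from which coefficient variances (global `N - 3` divisor),
#' \eqn{R^2_{DFA}(n) = 1 - F^2_\varepsilon(n)/F^2_Y(n)}, standardized
#' coefficients and elasticities follow.
#'
#' Scales where the denominator \eqn{F^2_{X_1} F^2_{X_2} - (F^2_{X_1 X_2})^2}
#' is non-positive or below `1e-12` times \eqn{F^2_{X_1} F^2_{X_2}} are kept
#' in the table but flagged unusable (`usable = FALSE`, values `NA`).
#' \eqn{R^2_{DFA}(n)} is reported as computed, without clipping to
#' \eqn{[0, 1]}; out-of-range values are flagged in `r2_flagged`.
#'
#' @inheritParams ols_fit
#' @param grid Integer vector of scales; default 30 log-spaced scales in
#'   `[10, min(1000, N/4)]`.
#' @param order Polynomial detrend order (default 2).
#' @return Object of class `"dfa_fit"`: list with `table` (data.frame with
#'   columns `scale`, `beta1`, `beta2`, `var1`, `var2`, `fe2`, `f2_y`, `r2`,
#'   `beta_star1`, `beta_star2`, `eta1`, `eta2`, `usable`, `r2_flagged`),
#'   `N`, `order`, `grid` and the raw series means.
#' @examples
#' x1 <- gen_arfima(0.2, 2000, seed = 1)
#' x2 <- gen_arfima(0.2, 2000, seed = 2)
#' fit <- dfa_fit(1 + x1 + 2 * x2 + rnorm(2000), x1, x2)
#' average_over_scales(fit, 10, 500)
#' @export
dfa_fit <- function(y, x1, x2, grid = NULL, order = 2L) {
  check_series(y, min_len = 4L)
  check_series(x1, min_len = 4L)
  check_series(x2, min_len = 4L)
  N <- check_equal_length(y, x1, x2)
  order <- check_order(order)
  if (is.null(grid)) grid <- default_grid(N)
  grid <- check_grid(grid, N, order)
  profs <- cbind(compute_profile(y), compute_profile(x1), compute_profile(x2))
  mean_y <- mean(y); mean_x1 <- mean(x1); mean_x2 <- mean(x2)
  eta_defined <- mean_y != 0

  rows <- lapply(grid, function(n) {
    F <- fluct_matrix(profs, n, order)
    fyy <- F[1L, 1L]; f11 <- F[2L, 2L]; f22 <- F[3L, 3L]
    f12 <- F[2L, 3L]; f1y <- F[1L, 2L]; f2y <- F[1L, 3L]
    den <- f11 * f22 - f12 * f12
    if (!is.finite(den) || den <= 1e-12 * f11 * f22) {
      return(c(NA, NA, NA, NA, NA, fyy, NA, NA, NA, NA, NA, FALSE, FALSE))
    }
    b1 <- (f1y * f22 - f2y * f12) / den
    b2 <- (f2y * f11 - f1y * f12) / den
    e <- y - b1 * x1 - b2 * x2
    e <- e - mean(e)
    fe2 <- fluct_matrix(matrix(cumsum(e), ncol = 1L), n, order)[1L, 1L]
    r2 <- 1 - fe2 / fyy
    c(b1, b2,
      f22 * fe2 / den / (N - 3), f11 * fe2 / den / (N - 3),
      fe2, fyy, r2,
      b1 * sqrt(f11 / fyy), b2 * sqrt(f22 / fyy),
      if (eta_defined) b1 * mean_x1 / mean_y else NA_real_,
      if (eta_defined) b2 * mean_x2 / mean_y else NA_real_,
      TRUE, r2 < 0 || r2 > 1)
  })
  tab <- as.data.frame(do.call(rbind, rows))
  names(tab) <- c("beta1", "beta2", "var1", "var2", "fe2", "f2_y", "r2",
                  "beta_star1", "beta_star2", "eta1", "eta2",
                  "usable", "r2_flagged")
  tab$usable <- as.logical(tab$usable)
  tab$r2_flagged <- as.logical(tab$r2_flagged)
  tab <- cbind(scale = grid, tab)
  structure(list(table = tab, grid = grid, N = N, order = order,
                 means = c(y = mean_y, x1 = mean_x1, x2 = mean_x2),
                 eta_defined = eta_defined),
            class = "dfa_fit")
}

#' @export
print.dfa_fit <- function(x, digits = 4, ...) {
  cat(sprintf(
    "DFA-based bivariate regression (N = %d, order-%d detrending, %d scales)\n",
    x$N, x$order, length(x$grid)))
  n_bad <- sum(!x$table$usable)
  if (n_bad > 0) cat(sprintf("  %d scale(s) flagged unusable\n", n_bad))
  print(format(x$table[, c("scale", "beta1", "beta2", "var1", "var2", "r2")],
               digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.dfa_fit <- function(x, ...) x$table

#' Average scale-dependent coefficients over a scale band
#'
#' Arithmetic mean of \eqn{\hat\beta_1(n)} and \eqn{\hat\beta_2(n)} over the
#' usable grid scales falling in the closed range `[n_low, n_high]` — the
#' summary used to compare scale-dependent estimates with scalar truth in
#' the simulation studies.
#'
#' @param fit A [dfa_fit()] result.
#' @param n_low,n_high Scale band (inclusive).
#' @return Named numeric vector `c(beta1 =, beta2 =)`.
#' @export
average_over_scales <- function(fit, n_low, n_high) {
  if (!inherits(fit, "dfa_fit")) stop_input("fit must be a dfa_fit object")
  sel <- fit$table$scale >= n_low & fit$table$scale <= n_high &
    fit$table$usable
  if (!any(sel)) {
    stop_param("no usable scales in [%s, %s]", format(n_low), format(n_high))
  }
  c(beta1 = mean(fit$table$beta1[sel]), beta2 = mean(fit$table$beta2[sel]))
}
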