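#' Moving-average weights of fractionally integrated noise
#'
#' Coefficients of the MA(infinity) representation of an ARFIMA(0, d, 0)
#' process, \eqn{X_t = \sum_{n \ge 0} w_n \xi_{t-n}} with
#' \eqn{w_n = \Gamma(n + d) / [\Gamma(d)\,\Gamma(n + 1)]}. They are computed
#' by the stable recursion \eqn{w_n = w_{n-1} (n - 1 + d) / n}, which avoids
#' Gamma-function overflow for large `count`. Positive `d` gives persistent
#' (long-memory) series with Hurst exponent \eqn{H = d + 0.5}.
#'
#' @param d Fractional integration parameter, strictly inside (-0.5, 0.5).
#'   `d = 0` reduces to white noise (all weights after the first are zero).
#' @param count Number of weights to return (>= 1).
#' @return Numeric vector `w[1..count]` with `w[1] = 1`.
#' @examples
#' arfima_coefficients(0.4, 5)
#' @export
arfima_coefficients <- function(d, count) {
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) ||
      d <= -0.5 || d >= 0.5) {
    stop_param("d must lie strictly inside (-0.5, 0.5), got %s", format(d))
  }
  count <- as.integer(count)
  if (is.na(count) || count < 1L) stop_param("count must be a positive integer")
  w <- numeric(count)
  w[1L] <- 1
  if (count > 1L) {
    n <- seq_len(count - 1L)
    w <- cumprod(c(1, (n - 1 + d) / n))
  }
  w
}

#' Simulate fractionally integrated noise (ARFIMA(0, d, 0))
#'
#' Generates a long-memory Gaussian series as a truncated moving average of
#' i.i.d. standard normal innovations with weights from
#' [arfima_coefficients()]. `truncation - 1` extra innovations are drawn
#' before the first output so that every output point uses a full-length
#' weight window; no burn-in is discarded and there is no startup transient.
#' The convolution is evaluated by FFT.
#'
#' @param d Fractional integration parameter in (-0.5, 0.5).
#' @param length Number of output points (>= 1).
#' @param seed Optional RNG seed; the caller's RNG state is restored on exit.
#' @param truncation Number of MA weights retained (default: `length`).
#' @return Numeric vector of the stated length.
#' @examples
#' x <- gen_arfima(0.4, 1000, seed = 1)
#' @export
gen_arfima <- function(d, length, seed = NULL, truncation = length) {
  length <- as.integer(length)
  if (is.na(length) || length < 1L) stop_param("length must be >= 1")
  truncation <- as.integer(truncation)
  if (is.na(truncation) || truncation < 1L) stop_param("truncation must be >= 1")
  w <- arfima_coefficients(d, truncation)
  m <- length + truncation - 1L
  xi <- with_seed(seed, stats::rnorm(m))
  if (truncation == 1L) return(xi)
  # linear convolution via zero-padded FFT; wrap-around cannot reach the
  # retained indices because nfft >= m + truncation - 1
  nfft <- stats::nextn(m + truncation - 1L, 2)
  conv <- Re(stats::fft(stats::fft(c(w, numeric(nfft - truncation))) *
                        stats::fft(c(xi, numeric(nfft - m))),
                        inverse = TRUE)) / nfft
  conv[truncation:(truncation + length - 1L)]
}

#' Binomial multifractal series with noise substitution
#'
#' Deterministic binomial cascade over indices \eqn{k = 1, \dots, 2^{n}}:
#' element k equals \eqn{p^{n - b(k-1)} (1-p)^{b(k-1)}}, where \eqn{b(\cdot)}
#' counts ones in the binary representation. Every raw value strictly below
#' `removal_threshold` is then replaced by a Gaussian(0, `noise_sd`) draw,
#' leaving a sparse cascade embedded in noise — the standard multifractal
#' test signal for scale-dependent estimators.
#'
#' @param p Cascade multiplier in (0, 0.5].
#' @param n_levels Cascade depth; the series has `2^n_levels` points
#'   (`n_levels <= 30`).
#' @param removal_threshold Lower cutoff below which raw values are
#'   substituted (default 1e-5). `0` disables substitution.
#' @param noise_sd Standard deviation of the substituted noise (default 1e-4).
#' @param seed Optional RNG seed for the substituted values.
#' @return Numeric vector of length `2^n_levels` with attributes `raw` (the
#'   pre-substitution cascade) and `substituted` (logical mask).
#' @examples
#' x <- gen_bmfs(0.3, 10, seed = 1)
#' sum(attr(x, "raw"))  # exactly 1
#' @export
gen_bmfs <- function(p, n_levels, removal_threshold = 1e-5, noise_sd = 1e-4,
                     seed = NULL) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0 || p > 0.5) {
    stop_param("p must lie in (0, 0.5], got %s", format(p))
  }
  n_levels <- as.integer(n_levels)
  if (is.na(n_levels) || n_levels < 1L) stop_param("n_levels must be >= 1")
  if (n_levels > 30L) {
    stop_param("n_levels = %d gives 2^%d points, beyond addressable size",
               n_levels, n_levels)
  }
  if (removal_threshold < 0) stop_param("removal_threshold must be >= 0")
  if (noise_sd <= 0) stop_param("noise_sd must be > 0")
  size <- 2L^n_levels
  m <- seq_len(size) - 1L
  bits <- integer(size)
  for (b in seq_len(n_levels)) {
    bits <- bits + m %% 2L
    m <- m %/% 2L
  }
  raw <- p^(n_levels - bits) * (1 - p)^bits
  out <- raw
  sub <- raw < removal_threshold
  if (any(sub)) {
    out[sub] <- with_seed(seed, stats::rnorm(sum(sub), mean = 0, sd = noise_sd))
  }
  structure(out, raw = raw, substituted = sub)
}

#' Synthetic three-city PM2.5-like fixture
#'
#' Generates three strictly positive, positively cross-correlated series that
#' emulate the structure of hourly PM2.5 records from three neighbouring
#' cities: a shared long-memory component (fractional noise with d = 0.3,
#' Hurst exponent 0.8), a shared sinusoidal seasonal cycle, an independent
#' long-memory component per site, all combined on the log scale around
#' city-specific base concentrations (70, 65 and 85 ug/m3). This is a
#' synthetic stand-in used to exercise the pipeline; it is not real data and
#' carries no calendar alignment, missingness or weather covariates.
#'
#' @param length Number of time points (>= 100).
#' @param seed Optional RNG seed.
#' @param period Seasonal period in sampling units; default `length / 3`
#'   (three full cycles over the record, as in a three-year hourly span).
#' @return A data.frame with numeric columns `beijing`, `tianjin`, `baoding`.
#' @export
gen_pm25_fixture <- function(length, seed = NULL, period = length / 3) {
  length <- as.integer(length)
  if (is.na(length) || length < 100L) stop_param("length must be >= 100")
  if (!is.numeric(period) || period <= 0) stop_param("period must be > 0")
  base <- c(beijing = 70, tianjin = 65, baoding = 85)
  season <- sin(2 * pi * seq_len(length) / period)
  with_seed(seed, {
    common <- gen_arfima(0.3, length)
    cols <- lapply(seq_len(3L), function(i) {
      own <- gen_arfima(0.3, length)
      base[i] * exp(0.45 * common + 0.30 * own + 0.40 * season)
    })
    names(cols) <- names(base)
    as.data.frame(cols)
  })
}
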