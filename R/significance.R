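# Surrogate-shuffle significance machinery. Shuffling destroys serial and
# cross dependence while preserving marginal distributions; repeating the
# scale-dependent fit on shuffled surrogates yields an empirical null for
# the per-scale statistics, from which per-scale critical values are read
# off as quantiles. A single critical value from the t(N - 3) table would be
# wrong here because the effective information per scale varies with n.

#' Scale-dependent t-statistics of a DFA regression fit
#'
#' \eqn{t_j(n) = (\hat\beta_j(n) - \beta_j^0) / \sqrt{var(\hat\beta_j(n))}}
#' for j = 1, 2 against the null values `null_beta1`, `null_beta2`
#' (defaults 0). Scales flagged unusable in the fit, or with non-positive
#' variance, yield `NA`.
#'
#' @param fit A [dfa_fit()] result.
#' @param null_beta1,null_beta2 Null-hypothesis coefficient values.
#' @return Object of class `"scale_t"`: list with `table` (columns `scale`,
#'   `t1`, `t2`) and the null values.
#' @export
scale_t_statistics <- function(fit, null_beta1 = 0, null_beta2 = 0) {
  if (!inherits(fit, "dfa_fit")) stop_input("fit must be a dfa_fit object")
  tab <- fit$table
  ok1 <- tab$usable & is.finite(tab$var1) & tab$var1 > 0
  ok2 <- tab$usable & is.finite(tab$var2) & tab$var2 > 0
  t1 <- ifelse(ok1, (tab$beta1 - null_beta1) / sqrt(tab$var1), NA_real_)
  t2 <- ifelse(ok2, (tab$beta2 - null_beta2) / sqrt(tab$var2), NA_real_)
  structure(list(table = data.frame(scale = tab$scale, t1 = t1, t2 = t2),
                 null = c(null_beta1, null_beta2)),
            class = "scale_t")
}

#' @export
print.scale_t <- function(x, ...) {
  cat(sprintf("Scale-dependent t-statistics (null beta = %g, %g)\n",
              x$null[1], x$null[2]))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Random permutation surrogate of a series
#'
#' Uniform random permutation of the values; the multiset of values is
#' preserved exactly, all serial structure is destroyed.
#'
#' @param x Numeric series (length >= 2).
#' @param seed Optional RNG seed; caller's RNG state restored on exit.
#' @return Permuted numeric vector.
#' @export
shuffle_series <- function(x, seed = NULL) {
  check_series(x, min_len = 2L)
  with_seed(seed, x[sample.int(length(x))])
}

# nearest-rank upper quantile; by convention 0 when the level collapses
# (alpha = 1: zero-width acceptance region)
nearest_rank_quantile <- function(v, level) {
  k <- ceiling(level * length(v))
  if (k < 1L) return(0)
  sort(v)[k]
}

#' Per-scale critical values for the regression t-statistics
#'
#' Monte-Carlo critical curve \eqn{t^c(n)} under the joint null of no serial
#' and no cross dependence: in each of `n_shuffles` replicates all three
#' series are independently permuted, the DFA regression is refitted, and
#' the two t-statistics under null coefficients 0 are pooled. The critical
#' value at scale n is the empirical `1 - alpha` nearest-rank quantile of
#' the pooled \eqn{|t(n)|} — for a symmetric null this equals the two-sided
#' acceptance bound with tail mass `alpha`. An observed \eqn{|t_j(n)|}
#' above the curve rejects \eqn{\beta_j = 0} at that scale.
#'
#' Reproducibility contract: the master `seed` generates per-replicate child
#' seeds as `sample.int(2147483646, n_shuffles)` and each replicate runs
#' under its own child seed, so results are independent of scheduling.
#'
#' @inheritParams dfa_fit
#' @param alpha Significance level in (0, 1] (default 0.01).
#' @param n_shuffles Number of shuffle replicates (>= 100; default 10000).
#' @param seed Master RNG seed.
#' @return Object of class `"critical_curve"`: list with `table` (columns
#'   `scale`, `critical`, `n_finite`, `flagged`), `alpha`, `n_shuffles`,
#'   `statistic`, `seed`. Scales with more than 50% unusable replicates are
#'   flagged.
#' @export
critical_curve_t <- function(y, x1, x2, grid = NULL, order = 2L,
                             alpha = 0.01, n_shuffles = 10000L, seed = NULL) {
  N <- check_equal_length(y, x1, x2)
  if (is.null(grid)) grid <- default_grid(N)
  grid <- check_grid(grid, N, check_order(order))
  check_alpha(alpha)
  n_shuffles <- as.integer(n_shuffles)
  if (is.na(n_shuffles) || n_shuffles < 100L) {
    stop_param("n_shuffles must be >= 100")
  }
  seeds <- child_seeds(seed, n_shuffles)
  stats <- vapply(seeds, function(s) {
    with_seed(s, {
      fit <- dfa_fit(y[sample.int(N)], x1[sample.int(N)], x2[sample.int(N)],
                     grid = grid, order = order)
      tt <- scale_t_statistics(fit)$table
      as.vector(rbind(tt$t1, tt$t2))  # per-scale (t1, t2) pairs, pooled later
    })
  }, numeric(2L * length(grid)))
  build_curve(stats, grid, alpha, n_shuffles, "t", seed, absolute = TRUE)
}

#' Per-scale critical values for the partial DCCA coefficient
#'
#' Same shuffle machinery as [critical_curve_t()] with
#' \eqn{\rho_{PDCCA}(n)} of the stated pair as the statistic and a
#' one-sided upper `1 - alpha` nearest-rank quantile: an observed
#' coefficient below the curve shows no significant cross-correlation at
#' that scale.
#'
#' @inheritParams critical_curve_t
#' @param series_list List of equal-length numeric series (m >= 2).
#' @param pair Length-2 integer vector: indices of the pair of interest.
#' @return Object of class `"critical_curve"` with `statistic =
#'   "rho_pdcca"`.
#' @export
critical_curve_pdcca <- function(series_list, pair, grid = NULL, order = 2L,
                                 alpha = 0.01, n_shuffles = 10000L,
                                 seed = NULL) {
  if (!is.list(series_list) || length(series_list) < 2L) {
    stop_input("series_list must be a list of at least two series")
  }
  N <- do.call(check_equal_length, series_list)
  if (is.null(grid)) grid <- default_grid(N)
  grid <- check_grid(grid, N, check_order(order))
  check_alpha(alpha)
  n_shuffles <- as.integer(n_shuffles)
  if (is.na(n_shuffles) || n_shuffles < 100L) {
    stop_param("n_shuffles must be >= 100")
  }
  pair <- as.integer(pair)
  if (length(pair) != 2L) stop_input("pair must contain two indices")
  seeds <- child_seeds(seed, n_shuffles)
  stats <- vapply(seeds, function(s) {
    with_seed(s, {
      shuffled <- lapply(series_list, function(z) z[sample.int(N)])
      vapply(grid, function(n) {
        tryCatch(rho_pdcca(shuffled, pair[1L], pair[2L], n, order),
                 dfareg_degenerate_error = function(e) NA_real_)
      }, numeric(1))
    })
  }, numeric(length(grid)))
  build_curve(stats, grid, alpha, n_shuffles, "rho_pdcca", seed,
              absolute = FALSE)
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    stop_param("alpha must lie in (0, 1]")
  }
}

# stats: matrix with one column per replicate; rows are per-scale values
# (2 per scale for pooled t, 1 per scale for rho).
build_curve <- function(stats, grid, alpha, n_shuffles, statistic, seed,
                        absolute) {
  per_scale <- nrow(stats) / length(grid)
  rows <- lapply(seq_along(grid), function(g) {
    v <- as.vector(stats[seq.int((g - 1L) * per_scale + 1L, g * per_scale), ])
    v <- v[is.finite(v)]
    n_fin <- length(v)
    flagged <- n_fin < 0.5 * per_scale * n_shuffles
    crit <- if (n_fin == 0L) NA_real_ else {
      nearest_rank_quantile(if (absolute) abs(v) else v, 1 - alpha)
    }
    data.frame(scale = grid[g], critical = crit, n_finite = n_fin,
               flagged = flagged)
  })
  structure(list(table = do.call(rbind, rows), alpha = alpha,
                 n_shuffles = n_shuffles, statistic = statistic,
                 seed = seed),
            class = "critical_curve")
}

#' @export
print.critical_curve <- function(x, ...) {
  cat(sprintf(
    "Per-scale critical values of %s (alpha = %g, %d shuffle replicates)\n",
    if (x$statistic == "t") "|t(n)|" else "rho_PDCCA(n)",
    x$alpha, x$n_shuffles))
  print(x$table, row.names = FALSE)
  invisible(x)
}
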