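# Independent straight-loop reference implementations used as oracles.
# These deliberately share no code with the package: profiles by explicit
# accumulation, windows by explicit index arithmetic, trends by lm() per
# window.

oracle_profile <- function(z) {
  out <- numeric(length(z))
  acc <- 0
  mu <- mean(z)
  for (t in seq_along(z)) {
    acc <- acc + z[t] - mu
    out[t] <- acc
  }
  out
}

oracle_windows <- function(N, n) {
  n_seg <- N %/% n
  fwd <- lapply(seq_len(n_seg), function(j) ((j - 1) * n + 1):((j - 1) * n + n))
  bwd <- lapply(seq_len(n_seg), function(j) (N - j * n + 1):(N - j * n + n))
  c(fwd, bwd)
}

# F^2 between two profiles at one scale: per-window polynomial fit via lm,
# mean within-window residual product (divisor n), mean over windows.
oracle_f2 <- function(prof_a, prof_b, n, order = 2) {
  wins <- oracle_windows(length(prof_a), n)
  vals <- vapply(wins, function(ix) {
    k <- seq_along(ix)
    ra <- stats::residuals(stats::lm(prof_a[ix] ~ stats::poly(k, order, raw = TRUE)))
    rb <- stats::residuals(stats::lm(prof_b[ix] ~ stats::poly(k, order, raw = TRUE)))
    sum(ra * rb) / n
  }, numeric(1))
  mean(vals)
}

oracle_dfa_variance <- function(z, n, order = 2) {
  p <- oracle_profile(z)
  oracle_f2(p, p, n, order)
}

oracle_dcca_covariance <- function(a, b, n, order = 2) {
  oracle_f2(oracle_profile(a), oracle_profile(b), n, order)
}

# Scale-dependent regression coefficients assembled by hand from the six
# oracle fluctuation values.
oracle_dfa_betas <- function(y, x1, x2, n, order = 2) {
  py <- oracle_profile(y); p1 <- oracle_profile(x1); p2 <- oracle_profile(x2)
  f11 <- oracle_f2(p1, p1, n, order); f22 <- oracle_f2(p2, p2, n, order)
  f12 <- oracle_f2(p1, p2, n, order)
  f1y <- oracle_f2(p1, py, n, order); f2y <- oracle_f2(p2, py, n, order)
  den <- f11 * f22 - f12^2
  c(beta1 = (f1y * f22 - f2y * f12) / den,
    beta2 = (f2y * f11 - f1y * f12) / den)
}

# Explicit 3x3 inverse via the adjugate, for the partial-DCCA oracle.
oracle_pdcca3 <- function(R, i, j) {
  adj <- matrix(0, 3, 3)
  for (r in 1:3) for (s in 1:3) {
    minor <- R[-r, -s, drop = FALSE]
    adj[s, r] <- (-1)^(r + s) * (minor[1, 1] * minor[2, 2] -
                                 minor[1, 2] * minor[2, 1])
  }
  C <- adj / (R[1, 1] * adj[1, 1] + R[1, 2] * adj[2, 1] + R[1, 3] * adj[3, 1])
  -C[i, j] / sqrt(C[i, i] * C[j, j])
}
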