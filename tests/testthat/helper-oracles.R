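# Independent oracles and small builders shared across tests.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force two-line change-point scan using lm() on both sides.
# Returns the split index (last point of the left segment) and total SSE.
oracle_changepoint_scan <- function(t, y, min_pts = 3) {
  n <- length(t)
  best_k <- NA_integer_
  best_sse <- Inf
  for (k in min_pts:(n - min_pts)) {
    sse <- sum(stats::resid(stats::lm(y[1:k] ~ t[1:k]))^2) +
      sum(stats::resid(stats::lm(y[(k + 1):n] ~ t[(k + 1):n]))^2)
    if (sse < best_sse - 1e-12) {
      best_sse <- sse
      best_k <- k
    }
  }
  list(index = best_k, sse = best_sse)
}

# Grid-search oracle for the coupled equipartition/WLC solve: minimizes the
# absolute residual of wlc_force(l) - kB*T*l/var_y over a dense grid in l.
oracle_grid_solve <- function(var_y, p = wlc_params(), n_grid = 1e6) {
  kB <- 1.380649e-23
  l <- seq(p$l0 * 1e-6, p$l0 * (1 - 1e-6), length.out = n_grid)
  resid <- abs(wlc_force(l, p) - kB * p$T * l / var_y)
  i <- which.min(resid)
  list(l = l[i], F = kB * p$T * l[i] / var_y)
}

# Minimal valid molecule record.
tiny_record <- function(uid = fmt_uuid(1), n = 3, t0 = 0) {
  mol_record(uid, data.frame(t_s = t0 + seq_len(n) * 0.25,
                             frame = seq_len(n) - 1L,
                             x_um = stats::rnorm(n, 10, 0.1),
                             y_um = stats::rnorm(n, 10, 0.1)))
}

# Sampled (pixel-center) Gaussian spot image, for exact-recovery tests.
sampled_gaussian_patch <- function(nr, nc, A, B, s, x0, y0) {
  xs <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  ys <- matrix(rep(0:(nr - 1), times = nc), nr, nc)
  B + A * exp(-((xs - x0)^2 + (ys - y0)^2) / (2 * s^2))
}
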