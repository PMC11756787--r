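# Independent numerical oracles used by the tests. These deliberately use
# different algorithms from the package implementation (fixed-grid
# trapezoid quadrature instead of adaptive quadrature / closed-form
# kernels) so agreement is a genuine cross-check.

# one-sided JZS Bayes factor by brute-force trapezoid quadrature over the
# standardized effect size
oracle_bf_quadrature <- function(t_stat, n, r = sqrt(2) / 2,
                                 direction = "greater") {
  ub <- max(8, abs(t_stat) / sqrt(n) + 12 / sqrt(n))
  grid <- seq(0, ub, length.out = 200001L)
  if (direction == "less") grid <- -grid
  lik <- suppressWarnings(
    stats::dt(t_stat, df = n - 1, ncp = sqrt(n) * grid)
  )
  dens <- lik * 2 * stats::dcauchy(grid, 0, r)
  step <- abs(grid[2] - grid[1])
  m1 <- sum((dens[-1] + dens[-length(dens)]) / 2) * step
  m1 / stats::dt(t_stat, df = n - 1)
}

# trailing weighted average by 1 ms trapezoid quadrature of the printed
# integral, with piecewise-linear interpolation of the 100 ms series
oracle_smooth_trapezoid <- function(aai, idx, delta_tau = 3) {
  tt <- (seq_along(aai) - 1) * 0.1
  t0 <- tt[idx]
  span <- min(delta_tau, t0 - tt[1])
  if (span <= 0) {
    return(aai[idx])
  }
  tau <- seq(0, span, by = 0.001)
  f <- stats::approx(tt, aai, xout = t0 - tau, rule = 2)$y
  w <- 2 * (delta_tau - tau) / delta_tau^2
  trap <- function(y) sum((y[-1] + y[-length(y)]) / 2) * 0.001
  trap(f * w) / trap(w)
}
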