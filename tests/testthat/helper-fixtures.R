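# Shared fixtures, built in code.

# noisy hinge data with known breakpoint
make_hinge <- function(n = 200, psi = 2, b0 = 1, b1 = 0, b2 = 1.5,
                       sd = 0.05, xmax = 4, seed = 11) {
  set.seed(seed)
  x <- sort(runif(n, 0, xmax))
  y <- b0 + b1 * x + b2 * pmax(x - psi, 0) + rnorm(n, 0, sd)
  list(x = x, y = y, psi = psi)
}

# brute-force profiled-RSS breakpoint search (independent of fit_segmented)
brute_force_psi <- function(x, y, n_grid = 10000) {
  lo <- quantile(x, 0.05, names = FALSE)
  hi <- quantile(x, 0.95, names = FALSE)
  grid <- seq(lo, hi, length.out = n_grid)
  rss <- vapply(grid, function(p) {
    X <- cbind(1, x, pmax(x - p, 0))
    sum(lm.fit(X, y)$residuals^2)
  }, numeric(1))
  list(psi = grid[which.min(rss)], rss = min(rss),
       spacing = grid[2] - grid[1])
}

# brute-force single-predictor shifted power fit: grid over the exponent with
# per-exponent OLS for intercept and slope
brute_force_power <- function(x, y, c_grid = seq(0.1, 5, by = 0.001)) {
  best <- NULL
  for (cc in c_grid) {
    f <- lm.fit(cbind(1, x^cc), y)
    rss <- sum(f$residuals^2)
    if (is.null(best) || rss < best$rss)
      best <- list(a = f$coefficients[1], b = f$coefficients[2], c = cc,
                   rss = rss)
  }
  best
}

# independently coded BIC for re-ranking oracles
oracle_bic <- function(n, rss, k) if (rss <= 0) -Inf else n * log(rss / n) + k * log(n)
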