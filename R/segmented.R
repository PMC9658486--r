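# OLS of the hinge model y = b0 + b1*x + b2*(x - psi)_+ for fixed psi.
# Returns coefficients, RSS and the standard error of b2.
.hinge_ols <- function(x, y, psi, want_se = FALSE) {
  X <- cbind(1, x, pmax(x - psi, 0))
  fit <- tryCatch(stats::lm.fit(X, y), error = function(e) NULL)
  if (is.null(fit) || any(is.na(fit$coefficients)))
    return(list(rss = Inf, coef = c(NA, NA, NA), se2 = NA_real_))
  rss <- sum(fit$residuals^2)
  out <- list(rss = rss, coef = unname(fit$coefficients))
  if (want_se) {
    n <- length(y)
    df <- n - 3
    xtx_inv <- tryCatch(chol2inv(chol(crossprod(X))), error = function(e) NULL)
    out$se2 <- if (is.null(xtx_inv) || df <= 0) NA_real_
               else sqrt(max(rss / df, 0) * xtx_inv[3, 3])
    out$df <- df
  }
  out
}

#' Continuous two-segment (hinge) linear regression
#'
#' Fits `y = b0 + b1*x + b2*(x - psi)_+` by profiling the breakpoint: the
#' residual sum of squares is minimised over a grid of 200 interior
#' x-quantiles (5 to 95 percent), then refined by golden-section search. The
#' fitted curve is continuous at `psi`; the left slope is `b1`, the right
#' slope `b1 + b2`.
#'
#' @param x,y numeric vectors, `length(x) >= 6`, at least 4 distinct x.
#' @param n_grid number of profile grid points (default 200).
#' @param davies_m candidate breakpoints for the Davies slope-change test
#'   attached to the fit.
#' @return object of class `"segmented_fit"`: `psi`, `intercept`,
#'   `slope_left`, `slope_right`, `RSS`, `davies_p`, `wald_p` (Wald test on
#'   the slope change at the fitted `psi`), `n`, `degenerate` (breakpoint
#'   stuck at the search boundary), and `fitted_at_psi` (the fitted response
#'   at the breakpoint — the plateau level when the right segment is flat).
#' @export
#' @examples
#' x <- seq(0, 4, length.out = 50)
#' fit_segmented(x, pmax(x - 2, 0))
fit_segmented <- function(x, y, n_grid = 200, davies_m = 10) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 6)
    stop("domain error: need at least 6 observations", call. = FALSE)
  if (length(unique(x)) < 4)
    stop("domain error: need at least 4 distinct x values", call. = FALSE)

  lo <- stats::quantile(x, 0.05, names = FALSE)
  hi <- stats::quantile(x, 0.95, names = FALSE)
  if (lo >= hi) stop("domain error: degenerate x range", call. = FALSE)
  grid <- seq(lo, hi, length.out = n_grid)
  rss_g <- vapply(grid, function(p) .hinge_ols(x, y, p)$rss, numeric(1))
  i0 <- which.min(rss_g)

  # golden-section refinement between the neighbours of the grid minimiser
  a <- grid[max(i0 - 1, 1)]
  b <- grid[min(i0 + 1, n_grid)]
  gr <- (sqrt(5) - 1) / 2
  f <- function(p) .hinge_ols(x, y, p)$rss
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  for (it in seq_len(60)) {
    if (b - a < 1e-9 * max(1, abs(hi))) break
    if (f1 <= f2) { b <- c2; c2 <- c1; f2 <- f1
                    c1 <- b - gr * (b - a); f1 <- f(c1) }
    else { a <- c1; c1 <- c2; f1 <- f2
           c2 <- a + gr * (b - a); f2 <- f(c2) }
  }
  psi <- (a + b) / 2
  if (f(psi) > rss_g[i0]) psi <- grid[i0]

  final <- .hinge_ols(x, y, psi, want_se = TRUE)
  cf <- final$coef
  span <- hi - lo
  degenerate <- (psi - lo) < 1e-3 * span || (hi - psi) < 1e-3 * span

  wald_p <- if (is.na(final$se2) || final$se2 == 0) NA_real_ else
    2 * stats::pt(-abs(cf[3] / final$se2), df = final$df)

  structure(list(
    psi = psi,
    intercept = cf[1],
    slope_left = cf[2],
    slope_right = cf[2] + cf[3],
    slope_change = cf[3],
    fitted_at_psi = cf[1] + cf[2] * psi,
    RSS = final$rss,
    davies_p = davies_test(x, y, m = davies_m),
    wald_p = wald_p,
    n = n,
    degenerate = degenerate
  ), class = "segmented_fit")
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat(sprintf("segmented fit: psi = %.4g, slopes %.4g -> %.4g, RSS = %.4g\n",
              x$psi, x$slope_left, x$slope_right, x$RSS))
  cat(sprintf("  Davies p = %.3g, Wald p = %.3g%s\n", x$davies_p, x$wald_p,
              if (x$degenerate) "  [degenerate: breakpoint at boundary]" else ""))
  invisible(x)
}

#' Davies' test for a change in slope
#'
#' Tests `H0: no slope change` against a hinge alternative when the
#' breakpoint is unidentified under the null. The Wald statistic for the
#' hinge coefficient is evaluated at `m` equally spaced candidate breakpoints
#' in the interior x-range; the p-value is the Davies upper bound for the
#' maximum of the correlated statistics:
#' `p <= 2*Phi(-M) + V * exp(-M^2/2) / sqrt(2*pi)`, with `M` the largest
#' absolute statistic and `V` the total variation of the statistic over the
#' candidate grid.
#'
#' @param x,y numeric vectors (same requirements as [fit_segmented()]).
#' @param m number of candidate breakpoints, `>= 2` (default 10).
#' @return the (conservative) p-value.
#' @export
davies_test <- function(x, y, m = 10) {
  if (m < 2) stop("domain error: m must be at least 2", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 6)
    stop("domain error: need at least 6 observations", call. = FALSE)
  lo <- stats::quantile(x, 0.05, names = FALSE)
  hi <- stats::quantile(x, 0.95, names = FALSE)
  psis <- seq(lo, hi, length.out = m)
  tss <- sum((y - mean(y))^2)
  z <- vapply(psis, function(p) {
    h <- .hinge_ols(x, y, p, want_se = TRUE)
    # an (numerically) exact linear fit carries no slope-change evidence
    if (is.na(h$se2) || h$se2 == 0 || h$rss <= 1e-12 * max(tss, 1)) 0
    else h$coef[3] / h$se2
  }, numeric(1))
  M <- max(abs(z))
  V <- sum(abs(diff(z)))
  p <- 2 * stats::pnorm(-M) + V * exp(-M^2 / 2) / sqrt(2 * pi)
  min(max(p, 0), 1)
}

#' Fitted-curve points of a segmented fit
#'
#' Convenience hook for plotting/export: evaluates the fitted two-segment
#' line on a grid.
#'
#' @param fit a `segmented_fit`.
#' @param x_range `(min, max)` of the evaluation grid.
#' @param n number of points.
#' @return data.frame with columns `x`, `y`.
#' @export
segmented_curve <- function(fit, x_range, n = 101) {
  xg <- seq(x_range[1], x_range[2], length.out = n)
  yg <- fit$intercept + fit$slope_left * xg +
    (fit$slope_right - fit$slope_left) * pmax(xg - fit$psi, 0)
  data.frame(x = xg, y = yg)
}
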