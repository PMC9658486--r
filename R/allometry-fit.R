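#' Specify one candidate allometric model
#'
#' A model is an equation family applied to an ordered set of predictors for
#' one response. Families: `linear` (`Y = a + sum b_i X_i`), `ln_linear`
#' (`Y = a + sum b_i ln(X_i)`) and `power_sum` (`Y = a + sum b_i X_i^c_i`).
#' Responses are never transformed.
#'
#' @param response response name: one of `total`, `trunk`, `foliage`,
#'   `branches`, `fb`, `litter`, `SOM`, `C_tot`, `N_tot`, `P_tot`.
#' @param predictors character vector of 1-4 predictor names: `V`, `A`, `H`,
#'   `D` for single trees; `V`, `A`, `H_mean`, `D_mean`, `NrS` for stands.
#' @param family one of `"linear"`, `"ln_linear"`, `"power_sum"`.
#' @return an object of class `"model_spec"`.
#' @export
model_spec <- function(response, predictors,
                       family = c("linear", "ln_linear", "power_sum")) {
  family <- match.arg(family)
  responses <- c("total", "trunk", "foliage", "branches", "fb", "litter",
                 "SOM", "C_tot", "N_tot", "P_tot")
  if (!response %in% responses)
    stop("unknown response '", response, "'", call. = FALSE)
  preds <- c("V", "A", "H", "D", "H_mean", "D_mean", "NrS")
  if (length(predictors) < 1 || length(predictors) > 4 ||
      anyDuplicated(predictors) || !all(predictors %in% preds))
    stop("predictors must be 1-4 distinct names among ",
         paste(preds, collapse = ", "), call. = FALSE)
  structure(list(response = response, predictors = predictors,
                 family = family), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("%s ~ %s  [%s]\n", x$response,
              paste(x$predictors, collapse = " + "), x$family))
  invisible(x)
}

# Column aliases so that specs written in field notation (V, A, ...) resolve
# against both tree and stand tables.
.response_column <- function(response, data) {
  alias <- c(total = "total_dry", trunk = "trunk_dry", foliage = "foliage_dry",
             branches = "branch_dry", fb = "fb_dry", litter = "litter_kg_m2",
             SOM = "SOM_pct")
  col <- if (response %in% names(data)) response
         else if (response %in% names(alias) && alias[[response]] %in% names(data))
           alias[[response]]
         else NA_character_
  if (is.na(col))
    stop("response '", response, "' not found in data", call. = FALSE)
  col
}

.predictor_column <- function(pred, data) {
  alias <- c(V = "volume_m3", A = "area_m2")
  col <- if (pred %in% names(data)) pred
         else if (pred %in% names(alias) && alias[[pred]] %in% names(data))
           alias[[pred]]
         else NA_character_
  if (is.na(col))
    stop("predictor '", pred, "' not found in data", call. = FALSE)
  col
}

# Exact fits leave numerically tiny residuals; snap them to true zero so the
# RSS = 0 sentinel (BIC = -Inf) engages.
.snap_rss <- function(rss, y) {
  tss <- sum((y - mean(y))^2)
  if (rss < 1e-20 * max(tss, 1)) 0 else rss
}

.bic_value <- function(n, rss, k) {
  if (rss <= 0) return(-Inf)
  n * log(rss / n) + k * log(n)
}

#' BIC of a least-squares fit
#'
#' `BIC = n * ln(RSS/n) + k * ln(n)` with `k` the number of mean-function
#' parameters plus one for the error variance. The same formula is applied to
#' every family so values are comparable across the model zoo. `RSS = 0`
#' yields `-Inf`, which ranks first.
#'
#' @param fit an [fit_model()] result, or a sample size `n` when `rss` and
#'   `k` are given directly.
#' @param rss,k residual sum of squares and parameter count (including the
#'   error variance) when calling with bare numbers.
#' @return BIC value.
#' @export
model_bic <- function(fit, rss = NULL, k = NULL) {
  if (inherits(fit, "allom_fit")) {
    if (!fit$converged)
      stop("BIC requested for a non-converged fit", call. = FALSE)
    return(.bic_value(fit$n, fit$RSS, fit$k))
  }
  .bic_value(fit, rss, k)
}

.n_mean_params <- function(spec) {
  p <- length(spec$predictors)
  switch(spec$family, linear = p + 1, ln_linear = p + 1, power_sum = 2 * p + 1)
}

#' Fit one allometric model
#'
#' Linear and ln-linear families are fitted by ordinary least squares;
#' the shifted power family `Y = a + sum b_i X_i^c_i` by Levenberg-Marquardt
#' nonlinear least squares ([minpack.lm::nls.lm]), initialised from
#' per-predictor log-log OLS of `(Y - min(Y) + eps)` on `X_i` and from a
#' restart grid of common exponents (0.5, 1, 1.5, 2, 3); the best converged
#' restart wins. Responses are never transformed.
#'
#' @param spec a [model_spec()].
#' @param data data.frame holding the response and predictor columns (field
#'   names or their table aliases, e.g. `V`/`volume_m3`).
#' @return object of class `"allom_fit"`: `spec`, named `coefficients` (`a`,
#'   `b_<pred>`, and `c_<pred>` for the power family), `n`, `RSS`,
#'   `RMSE = sqrt(RSS/n)`, `k` (parameter count incl. error variance), `BIC`,
#'   `converged`, and the underlying `lm` object for OLS families.
#' @export
fit_model <- function(spec, data) {
  if (!inherits(spec, "model_spec")) stop("spec must be a model_spec",
                                          call. = FALSE)
  y <- data[[.response_column(spec$response, data)]]
  X <- sapply(spec$predictors,
              function(p) data[[.predictor_column(p, data)]])
  X <- matrix(X, ncol = length(spec$predictors),
              dimnames = list(NULL, spec$predictors))
  keep <- stats::complete.cases(y, X)
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  n <- length(y)
  k <- .n_mean_params(spec) + 1L
  if (n <= k - 1L)
    stop("domain error: n must exceed the number of parameters", call. = FALSE)
  if (spec$family %in% c("ln_linear", "power_sum") && any(X <= 0))
    stop("domain error: '", spec$family,
         "' requires strictly positive predictors", call. = FALSE)

  if (spec$family %in% c("linear", "ln_linear")) {
    Xu <- if (spec$family == "ln_linear") log(X) else X
    df <- data.frame(y = y, Xu)
    names(df) <- c("y", spec$predictors)
    lmfit <- stats::lm(stats::reformulate(spec$predictors, "y"), data = df)
    cf <- stats::coef(lmfit)
    coefs <- c(a = unname(cf[1]),
               stats::setNames(unname(cf[-1]), paste0("b_", spec$predictors)))
    rss <- .snap_rss(sum(stats::residuals(lmfit)^2), y)
    out <- list(spec = spec, coefficients = coefs, n = n, RSS = rss,
                RMSE = sqrt(rss / n), k = k, converged = TRUE, lm = lmfit)
  } else {
    out <- .fit_power_sum(spec, y, X, k)
  }
  out$BIC <- if (out$converged) .bic_value(n, out$RSS, k) else NA_real_
  class(out) <- "allom_fit"
  out
}

# OLS of y on X^c for fixed exponents; returns list(a, b, rss) or NULL.
.ols_given_exponents <- function(y, X, cexp) {
  Xp <- sweep(X, 2, cexp, `^`)
  fit <- tryCatch(stats::lm.fit(cbind(1, Xp), y), error = function(e) NULL)
  if (is.null(fit) || any(is.na(fit$coefficients))) return(NULL)
  list(a = fit$coefficients[1], b = fit$coefficients[-1],
       rss = sum(fit$residuals^2))
}

.fit_power_sum <- function(spec, y, X, k, maxiter = 200) {
  p <- ncol(X)
  n <- length(y)

  starts <- list()
  # log-log initialisation, per predictor
  eps <- 1e-6
  yl <- log(pmax(y - min(y) + eps, eps))
  c0 <- vapply(seq_len(p), function(j) {
    s <- tryCatch(stats::coef(stats::lm(yl ~ log(X[, j])))[2],
                  error = function(e) 1)
    if (!is.finite(s) || s <= 0.05) 1 else min(s, 6)
  }, numeric(1))
  starts[[1]] <- c0
  for (g in c(0.5, 1, 1.5, 2, 3)) starts[[length(starts) + 1]] <- rep(g, p)

  resid_fn <- function(par) {
    a <- par[1]; b <- par[2:(p + 1)]; cexp <- par[(p + 2):(2 * p + 1)]
    y - (a + as.vector(sweep(X, 2, cexp, `^`) %*% b))
  }

  best <- NULL
  for (st in starts) {
    init <- .ols_given_exponents(y, X, st)
    if (is.null(init)) next
    par0 <- c(init$a, init$b, st)
    res <- tryCatch(
      minpack.lm::nls.lm(par = par0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, ftol = 1e-10, ptol = 1e-10)),
      error = function(e) NULL)
    if (is.null(res)) next
    conv <- res$info %in% 1:4
    rss <- .snap_rss(sum(res$fvec^2), y)
    if (conv && (is.null(best) || rss < best$rss))
      best <- list(par = res$par, rss = rss)
  }

  if (is.null(best)) {
    return(list(spec = spec, coefficients = NULL, n = n, RSS = NA_real_,
                RMSE = NA_real_, k = k, converged = FALSE))
  }
  coefs <- c(a = best$par[1],
             stats::setNames(best$par[2:(p + 1)],
                             paste0("b_", spec$predictors)),
             stats::setNames(best$par[(p + 2):(2 * p + 1)],
                             paste0("c_", spec$predictors)))
  list(spec = spec, coefficients = coefs, n = n, RSS = best$rss,
       RMSE = sqrt(best$rss / n), k = k, converged = TRUE)
}

#' @export
print.allom_fit <- function(x, ...) {
  cat(format_equation(x), "\n")
  if (x$converged)
    cat(sprintf("  n = %d, RSS = %.4g, RMSE = %.4g, BIC = %.4g\n",
                x$n, x$RSS, x$RMSE, x$BIC))
  else cat("  (did not converge)\n")
  invisible(x)
}

#' Human-readable equation of a fitted model
#'
#' @param fit an `allom_fit`.
#' @param digits significant digits for coefficients.
#' @return a character scalar like `"total ~ 0.25 + 1.46 x V"`.
#' @export
format_equation <- function(fit, digits = 3) {
  if (!fit$converged) return(paste0(fit$spec$response, " ~ <not converged>"))
  cf <- fit$coefficients
  fmt <- function(v) signif(v, digits)
  terms <- vapply(fit$spec$predictors, function(pnm) {
    b <- cf[[paste0("b_", pnm)]]
    switch(fit$spec$family,
           linear = sprintf("%s x %s", fmt(b), pnm),
           ln_linear = sprintf("%s x ln(%s)", fmt(b), pnm),
           power_sum = sprintf("%s x %s^%s", fmt(b), pnm,
                               fmt(cf[[paste0("c_", pnm)]])))
  }, character(1))
  paste0(fit$spec$response, " ~ ", fmt(cf[["a"]]), " + ",
         paste(terms, collapse = " + "))
}

#' Predict from a fitted allometric model
#'
#' @param object an `allom_fit`.
#' @param newdata data.frame with the predictor columns (field names or table
#'   aliases).
#' @param ... unused.
#' @return numeric vector of point predictions (kg, or response units).
#' @export
predict.allom_fit <- function(object, newdata, ...) {
  if (!object$converged) stop("cannot predict from a non-converged fit",
                              call. = FALSE)
  cf <- object$coefficients
  X <- sapply(object$spec$predictors,
              function(p) newdata[[.predictor_column(p, newdata)]])
  X <- matrix(X, ncol = length(object$spec$predictors),
              dimnames = list(NULL, object$spec$predictors))
  acc <- rep(cf[["a"]], nrow(X))
  for (pnm in object$spec$predictors) {
    b <- cf[[paste0("b_", pnm)]]
    xi <- X[, pnm]
    acc <- acc + switch(object$spec$family,
                        linear = b * xi,
                        ln_linear = b * log(xi),
                        power_sum = b * xi^cf[[paste0("c_", pnm)]])
  }
  unname(acc)
}

#' Normal-theory interval for the mean response of a linear fit
#'
#' Only the `linear` family supports analytic intervals (the nonlinear
#' families would need resampling, which is out of scope).
#'
#' @param fit an `allom_fit` of family `"linear"`.
#' @param newdata data.frame of predictor values.
#' @param level confidence level (default 0.95).
#' @return data.frame with columns `fit`, `lo`, `hi`.
#' @export
prediction_interval <- function(fit, newdata, level = 0.95) {
  if (!inherits(fit, "allom_fit") || fit$spec$family != "linear" ||
      is.null(fit$lm))
    stop("unsupported operation: intervals are available for the linear ",
         "family only", call. = FALSE)
  nd <- as.data.frame(sapply(fit$spec$predictors, function(p)
    newdata[[.predictor_column(p, newdata)]], simplify = FALSE))
  names(nd) <- fit$spec$predictors
  pr <- stats::predict(fit$lm, newdata = nd, interval = "confidence",
                       level = level)
  data.frame(fit = pr[, "fit"], lo = pr[, "lwr"], hi = pr[, "upr"])
}
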