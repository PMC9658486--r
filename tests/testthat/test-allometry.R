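test_that("exact linear data are recovered with zero residual", {
  d <- data.frame(V = 1:10, total_dry = 2 + 3 * (1:10))
  f <- fit_model(model_spec("total", "V", "linear"), d)
  expect_equal(unname(f$coefficients[["a"]]), 2)
  expect_equal(unname(f$coefficients[["b_V"]]), 3)
  expect_equal(f$RSS, 0, tolerance = 1e-20)
  expect_equal(f$BIC, -Inf)
})

test_that("ln-linear fits regress on log-predictors without touching y", {
  x <- seq(1, 20, length.out = 30)
  d <- data.frame(A = x, foliage_dry = -2.48 + 3.83 * log(x))
  f <- fit_model(model_spec("foliage", "A", "ln_linear"), d)
  expect_equal(unname(f$coefficients[["a"]]), -2.48, tolerance = 1e-8)
  expect_equal(unname(f$coefficients[["b_A"]]), 3.83, tolerance = 1e-8)
  expect_error(fit_model(model_spec("foliage", "A", "ln_linear"),
                         transform(d, A = A - 5)), "positive")
})

test_that("noiseless shifted power data are recovered to 4 decimals", {
  x <- seq(0.5, 8, length.out = 60)
  d <- data.frame(V = x, total_dry = 1 + 2 * x^1.5)
  f <- fit_model(model_spec("total", "V", "power_sum"), d)
  expect_equal(unname(f$coefficients[["a"]]), 1, tolerance = 1e-4)
  expect_equal(unname(f$coefficients[["b_V"]]), 2, tolerance = 1e-4)
  expect_equal(unname(f$coefficients[["c_V"]]), 1.5, tolerance = 1e-4)
})

test_that("single-predictor power fit matches the exponent-grid oracle", {
  tr <- generate_trees(generator_config(n_trees = 60, seed = 8))
  f <- fit_model(model_spec("total", "V", "power_sum"), tr)
  oracle <- brute_force_power(tr$V, tr$total_dry)
  expect_lte(f$RSS, oracle$rss * (1 + 1e-6))
  expect_equal(unname(f$coefficients[["c_V"]]), oracle$c, tolerance = 2e-3)
})

test_that("BIC follows n*ln(RSS/n) + k*ln(n) and is monotone in RSS", {
  expect_equal(model_bic(10, 10, 3), 3 * log(10))     # 6.9078
  expect_equal(model_bic(10, 10, 3), 6.9078, tolerance = 1e-4)
  expect_equal(model_bic(50, 0, 4), -Inf)
  expect_lt(model_bic(20, 5, 3), model_bic(20, 8, 3))
  # one extra parameter at equal RSS costs ln(n)
  expect_equal(model_bic(30, 2, 4) - model_bic(30, 2, 3), log(30))
})

test_that("model zoo enumeration yields 42 tree and 90 stand specs", {
  tr_specs <- enumerate_models("trees", "total")
  st_specs <- enumerate_models("stands", "total")
  expect_length(tr_specs, 42)
  expect_length(st_specs, 90)
  key <- function(s) paste(s$family, paste(s$predictors, collapse = ","))
  expect_false(any(duplicated(vapply(tr_specs, key, character(1)))))
  expect_false(any(duplicated(vapply(st_specs, key, character(1)))))
  expect_true(all(vapply(tr_specs, function(s) length(s$predictors),
                         integer(1)) <= 3))
})

test_that("selection follows the BIC ladder and tie-break rules", {
  fake <- function(bic, npred, family = "linear", k = npred + 2) {
    structure(list(spec = model_spec("total", c("V", "A", "H")[seq_len(npred)],
                                     family),
                   coefficients = c(a = 0), n = 30, RSS = 1, RMSE = 1, k = k,
                   BIC = bic, converged = TRUE), class = "allom_fit")
  }
  # single candidate: best = parsimonious
  s <- select_models(list(fake(5, 2)))
  expect_equal(s$best$BIC, 5)
  expect_equal(s$parsimonious$BIC, 5)
  # equal BIC, 1 vs 2 predictors: both pick the 1-predictor fit
  s <- select_models(list(fake(7, 2), fake(7, 1)))
  expect_length(s$best$spec$predictors, 1)
  expect_length(s$parsimonious$spec$predictors, 1)
  # 1-var BIC 100 vs 2-var BIC 85: delta > 10 so both selections are 2-var
  s <- select_models(list(fake(100, 1), fake(85, 2)))
  expect_length(s$best$spec$predictors, 2)
  expect_length(s$parsimonious$spec$predictors, 2)
  # 1-var BIC 90 within 10 of 85: parsimonious drops to 1 predictor
  s <- select_models(list(fake(90, 1), fake(85, 2)))
  expect_length(s$best$spec$predictors, 2)
  expect_length(s$parsimonious$spec$predictors, 1)
  # family tie-break at equal BIC and parameter count
  s <- select_models(list(fake(5, 1, "ln_linear"), fake(5, 1, "linear")))
  expect_equal(s$best$spec$family, "linear")
  expect_error(select_models(list()), "selection error")
})

test_that("selection agrees with an independently coded BIC re-ranking", {
  tr <- generate_trees(generator_config(n_trees = 50, seed = 21))
  fits <- fit_zoo(tr, "trees", "total")
  conv <- Filter(function(f) f$converged, fits)
  bics <- vapply(conv, function(f) oracle_bic(f$n, f$RSS, f$k), numeric(1))
  expect_equal(vapply(conv, function(f) f$BIC, numeric(1)), bics)
  sel <- select_models(fits)
  expect_equal(sel$best$BIC, min(bics))
})

test_that("combined volumetric model pools trees and stands", {
  tr <- data.frame(V = 1:5, total_dry = 6 + 2 * (1:5))
  st <- data.frame(volume_m3 = 6:10, total_dry = 6 + 2 * (6:10))
  f <- fit_combined_volume_model(tr, st)
  expect_equal(unname(f$coefficients[["a"]]), 6, tolerance = 1e-10)
  expect_equal(unname(f$coefficients[["b_V"]]), 2, tolerance = 1e-10)
  expect_equal(f$RMSE, 0, tolerance = 1e-8)
  expect_error(fit_combined_volume_model(tr[1, ], st[0, ]), "domain error")
})

test_that("combined model on synthetic defaults sits in the field regime", {
  tr <- generate_trees(generator_config(seed = 42))
  st <- generate_stands(generator_config(seed = 42))$stands
  f <- fit_combined_volume_model(tr, st)
  slope <- unname(f$coefficients[["b_V"]])
  expect_gte(slope, 0.5)
  expect_lte(slope, 1.5)
  expect_gt(unname(f$coefficients[["a"]]), 0)
})

test_that("predictions evaluate the fitted equation", {
  d <- data.frame(V = 1:10, total_dry = 2 + 3 * (1:10))
  f <- fit_model(model_spec("total", "V", "linear"), d)
  expect_equal(predict(f, data.frame(V = 0)), 2, tolerance = 1e-10)
  x <- seq(0.5, 8, length.out = 40)
  dp <- data.frame(V = x, total_dry = 1 + 2 * x^1.5)
  fp <- fit_model(model_spec("total", "V", "power_sum"), dp)
  expect_equal(predict(fp, data.frame(V = 4)), 1 + 2 * 8, tolerance = 1e-3)
})

test_that("mean-response interval matches the textbook closed form", {
  set.seed(14)
  x <- c(1, 2, 3, 4, 5)
  y <- 1 + 0.5 * x + rnorm(5, 0, 0.3)
  d <- data.frame(V = x, total_dry = y)
  f <- fit_model(model_spec("total", "V", "linear"), d)
  x0 <- 2.5
  pr <- prediction_interval(f, data.frame(V = x0), level = 0.95)
  # closed form: yhat +- t_{n-2} * s * sqrt(1/n + (x0-xbar)^2 / Sxx)
  b <- coef(lm(y ~ x)); s <- summary(lm(y ~ x))$sigma
  Sxx <- sum((x - mean(x))^2)
  half <- qt(0.975, 3) * s * sqrt(1 / 5 + (x0 - mean(x))^2 / Sxx)
  yhat <- b[1] + b[2] * x0
  expect_equal(pr$fit, unname(yhat))
  expect_equal(pr$lo, unname(yhat - half))
  expect_equal(pr$hi, unname(yhat + half))
  # width shrinks with n at fixed x
  big <- data.frame(V = rep(x, 40), total_dry = rep(y, 40) + rnorm(200, 0, .01))
  fb <- fit_model(model_spec("total", "V", "linear"), big)
  prb <- prediction_interval(fb, data.frame(V = x0))
  expect_lt(prb$hi - prb$lo, pr$hi - pr$lo)
  # nonlinear families have no analytic interval
  xp <- seq(0.5, 8, length.out = 40)
  fp <- fit_model(model_spec("total", "V", "power_sum"),
                  data.frame(V = xp, total_dry = 1 + 2 * xp^1.5))
  expect_error(prediction_interval(fp, data.frame(V = 2)), "unsupported")
})

test_that("non-positive predictors under a log are rejected", {
  d <- data.frame(V = c(-1, 1:9), total_dry = 1:10)
  expect_error(fit_model(model_spec("total", "V", "power_sum"), d), "positive")
})

test_that("fit serialisation writes valid JSON", {
  d <- data.frame(V = 1:10, total_dry = 2 + 3 * (1:10) + rnorm(10, 0, .1))
  f <- fit_model(model_spec("total", "V", "linear"), d)
  path <- tempfile(fileext = ".json")
  write_fit_json(f, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$family, "linear")
  expect_equal(back$coefficients$a, unname(f$coefficients[["a"]]))
  expect_equal(back$n, 10)
})
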