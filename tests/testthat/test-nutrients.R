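chem_tree <- function() {
  ch <- reference_chemistry()
  se <- grep("_se$", names(ch))
  ch[se] <- lapply(ch[se], function(x) ifelse(is.na(x), NA, 0))
  gen <- generate_chemistry(generator_config(seed = 1,
                                             chemistry_means_ses = ch))
  gen[gen$unit == "tree", ]
}

test_that("pool totals are mass-weighted concentrations", {
  chem <- chem_tree()
  p <- pool_totals(c(trunk = 100), chem)
  expect_equal(p$C_tot, 43.2)                 # 100 kg at 43.2% C
  p2 <- pool_totals(c(trunk = 10, fb = 10), chem)
  expect_equal(p2$N_tot, 10 * 0.006 + 10 * 0.022)   # 0.28 kg
  expect_equal(p2$FBMF, 0.5)
  expect_equal(p2$TMF, 0.5)
  expect_equal(p2$CN_total, p2$C_tot / p2$N_tot)
})

test_that("zero masses and missing chemistry raise explicit errors", {
  chem <- chem_tree()
  expect_error(pool_totals(c(trunk = 0, fb = 0), chem), "zero")
  expect_error(pool_totals(c(trunk = 10, root = 5), chem), "missing chemistry")
  expect_error(pool_totals(c(trunk = 10, fb = 5, branch = 2), chem),
               "not both")
})

test_that("pool totals are additive and homogeneous in mass", {
  chem <- chem_tree()
  a <- pool_totals(c(trunk = 20, foliage = 5), chem)
  b <- pool_totals(c(trunk = 40, foliage = 10), chem)
  expect_equal(b$C_tot, 2 * a$C_tot)
  expect_equal(b$N_tot, 2 * a$N_tot)
  t1 <- pool_totals(c(trunk = 20), chem)
  f1 <- pool_totals(c(foliage = 5), chem)
  expect_equal(a$C_tot, t1$C_tot + f1$C_tot)
})

test_that("mixture C/N lies between the compartment ratios", {
  chem <- chem_tree()
  cn_trunk <- 43.2 / 0.6
  cn_fb <- 47.7 / 2.2
  p <- pool_totals(c(trunk = 30, fb = 12), chem)
  expect_gt(p$CN_total, min(cn_trunk, cn_fb))
  expect_lt(p$CN_total, max(cn_trunk, cn_fb))
})

test_that("phosphorus totals use only compartments with P values", {
  chem <- chem_tree()
  p <- pool_totals(c(trunk = 100, foliage = 10), chem)
  expect_equal(p$P_tot, 100 * 0.8 / 1000 + 10 * 2.4 / 1000)
  # stand chemistry has no P at all -> NA
  gen <- generate_chemistry(generator_config(seed = 1))
  ps <- pool_totals(c(trunk = 50, fb = 20), gen[gen$unit == "stand", ])
  expect_true(is.na(ps$P_tot))
})

test_that("nutrient totals append per-row and respect conservation", {
  tr <- generate_trees(generator_config(n_trees = 20, seed = 6))
  chem <- generate_chemistry(generator_config(seed = 6))
  tr2 <- add_nutrient_totals(tr, chem, "tree")
  expect_true(all(c("C_tot", "N_tot", "P_tot") %in% names(tr2)))
  ct <- chem[chem$unit == "tree", ]
  cc <- function(t) ct$C_pct[ct$tissue == t] / 100
  manual <- tr$trunk_dry * cc("trunk") + tr$branch_dry * cc("branch") +
    tr$foliage_dry * cc("foliage")
  expect_equal(tr2$C_tot, manual)
})

test_that("exact power-law partitioning recovers its exponent", {
  bm <- seq(1, 80, length.out = 50)
  f <- fit_partitioning(bm, 2 * bm^0.75)
  expect_equal(unname(f$coefficients[["c_V"]]), 0.75, tolerance = 1e-5)
  expect_equal(unname(f$coefficients[["a"]]), 0, tolerance = 1e-4)
  expect_error(fit_partitioning(c(1, 2, 3), c(1, 2, 3)), "n >= 4")
  expect_error(fit_partitioning(c(-1, 1, 2, 3), 1:4), "positive")
})

test_that("partitioning exponent on generator defaults is near theory", {
  tr <- generate_trees(generator_config(n_trees = 300, seed = 42))
  f <- fit_partitioning(tr$total_dry, tr$fb_dry)
  chat <- unname(f$coefficients[["c_V"]])
  expect_gte(chat, 0.65)
  expect_lte(chat, 0.85)
  # Wald-type check against the theoretical 0.75: refit residual variance
  resid <- tr$fb_dry - predict(f, data.frame(V = tr$total_dry))
  expect_lt(abs(chat - 0.75), 0.12)
  expect_gt(sd(resid), 0)
})

test_that("dry mass applies the dry-matter fraction", {
  expect_equal(dry_mass(100, 0.5), 50)
  expect_equal(dry_mass(0, 0.3), 0)
  expect_equal(dry_mass(52847, 0.6031), 31872, tolerance = 1e-4)
  expect_error(dry_mass(10, 1.2), "domain error")
  expect_error(dry_mass(10, 0), "domain error")
})
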