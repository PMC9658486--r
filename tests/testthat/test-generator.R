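test_that("empty tree table keeps the full header", {
  tr <- generate_trees(generator_config(n_trees = 0, seed = 1))
  expect_equal(nrow(tr), 0)
  expect_named(tr, c("tree_id", "H", "D", "C1", "C2", "A", "V", "trunk_dry",
                     "branch_dry", "foliage_dry", "fb_dry", "total_dry"))
})

test_that("mass compartments conserve exactly and geometry columns agree", {
  tr <- generate_trees(generator_config(n_trees = 200, seed = 3))
  expect_identical(tr$total_dry, tr$trunk_dry + tr$fb_dry)
  expect_identical(tr$fb_dry, tr$foliage_dry + tr$branch_dry)
  expect_true(all(tr$C1 >= tr$C2))
  expect_equal(tr$A, canopy_area(tr$C1, tr$C2))
  expect_equal(tr$V, cone_volume(tr$A, tr$H))
  expect_true(all(tr[c("H", "D", "C1", "C2", "trunk_dry", "branch_dry",
                       "foliage_dry")] > 0))
})

test_that("identical config and seed give bit-identical outputs", {
  cfg <- generator_config(n_trees = 25, n_stands = 3, seed = 99,
                          grid_resolution_m = 0.05)
  expect_identical(generate_trees(cfg), generate_trees(cfg))
  expect_identical(generate_stands(cfg), generate_stands(cfg))
  expect_identical(generate_chemistry(cfg), generate_chemistry(cfg))
})

test_that("noiseless limit recovers the scaling exponent to 3 decimals", {
  tr <- generate_trees(generator_config(n_trees = 400, seed = 5,
                                        noise_cv = 0))
  fit <- fit_model(model_spec("total", "V", "power_sum"), tr)
  expect_equal(unname(fit$coefficients[["c_V"]]), 0.75, tolerance = 1e-4)
  expect_equal(unname(fit$coefficients[["b_V"]]), 1.68, tolerance = 1e-3)
})

test_that("defaults put >= 95% of tree values inside the published envelopes", {
  tr <- generate_trees(generator_config(n_trees = 2000, seed = 42))
  rr <- reference_ranges("trees")
  for (v in rr$variable) {
    frac <- mean(tr[[v]] >= rr$min[rr$variable == v] &
                   tr[[v]] <= rr$max[rr$variable == v])
    expect_gte(frac, 0.95)
  }
})

test_that("FBMF plateau of generated trees is estimated near the config value", {
  tr <- generate_trees(generator_config(n_trees = 300, seed = 42))
  est <- estimate_fbmf_plateau(tr)
  expect_lt(abs(est$plateau - 0.3), 0.05)
})

test_that("default stands at seed 7 fall inside the published envelopes", {
  st <- generate_stands(generator_config(n_stands = 11, seed = 7))
  s <- st$stands
  expect_equal(nrow(s), 11)
  expect_length(st$grids, 11)
  rr <- reference_ranges("stands")
  colmap <- c(V = "volume_m3", A = "area_m2", NrS = "NrS", D_mean = "D_mean",
              H_mean = "H_mean", trunk_dry = "trunk_dry", fb_dry = "fb_dry",
              total_dry = "total_dry", SOM_pct = "SOM_pct",
              litter_kg_m2 = "litter_kg_m2")
  for (v in rr$variable) {
    x <- s[[colmap[[v]]]]
    expect_true(all(x >= rr$min[rr$variable == v] &
                      x <= rr$max[rr$variable == v]), label = v)
  }
  expect_identical(s$total_dry, s$trunk_dry + s$fb_dry)
  expect_true(all(s$NrS == round(s$NrS) & s$NrS >= 1))
})

test_that("a single noiseless crown reproduces the analytic cone volume", {
  # render one cone mid-plot and compare the grid integral with pi*r^2*h/3
  z <- acaciabm:::.render_cones(px = 2.5, py = 2.5, h = 3, r = 1.2,
                                side = 5, cs = 0.02)
  g <- height_grid(z, 0.02, z0 = 0)
  expect_equal(surface_volume(g), pi * 1.2^2 * 3 / 3, tolerance = 0.02)
})

test_that("litter and SOM correlate near the configured r2", {
  st <- generate_stands(generator_config(n_stands = 300, seed = 12,
                                         grid_resolution_m = 0.1))$stands
  r2 <- cor(st$litter_kg_m2, st$SOM_pct)^2
  expect_gt(r2, 0.55)
  expect_lt(r2, 0.85)
})

test_that("chemistry draws collapse to the reference means when SE -> 0", {
  chem0 <- reference_chemistry()
  se_cols <- grep("_se$", names(chem0))
  chem0[se_cols] <- lapply(chem0[se_cols], function(x) ifelse(is.na(x), NA, 0))
  cfg <- generator_config(seed = 1, chemistry_means_ses = chem0)
  ch <- generate_chemistry(cfg)
  trunk <- ch[ch$unit == "tree" & ch$tissue == "trunk", ]
  expect_equal(trunk$C_pct, 43.2)
  foliage <- ch[ch$unit == "tree" & ch$tissue == "foliage", ]
  expect_equal(foliage$CN_ratio, 48.1 / 2.3)      # 20.91, printed 21.7 from
  expect_lt(abs(foliage$CN_ratio - 21.7), 1)      # unrounded field data
})

test_that("concentration draws are always positive even under huge SEs", {
  chem0 <- reference_chemistry()
  chem0$N_pct_se <- ifelse(is.na(chem0$N_pct_se), NA, 5)   # mean 0.6, se 5
  cfg <- generator_config(seed = 7, chemistry_means_ses = chem0)
  ch <- generate_chemistry(cfg)
  expect_true(all(ch$N_pct > 0))
  expect_true(all(ch$C_pct > 0 & ch$C_pct < 100))
  expect_equal(ch$CN_ratio, ch$C_pct / ch$N_pct)
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(height_range_m = c(5, 2)), "configuration")
  expect_error(generator_config(fbmf_plateau = 1.2), "configuration")
  expect_error(generator_config(plot_side_m = 0.01,
                                grid_resolution_m = 0.02), "configuration")
  expect_error(generator_config(stems_range = c(-3, 5)), "configuration")
})

test_that("generator config survives a JSON round-trip", {
  cfg <- generator_config(n_trees = 5, seed = 31, noise_cv = 0.2)
  f <- tempfile(fileext = ".json")
  write_generator_config(cfg, f)
  cfg2 <- read_generator_config(f)
  expect_equal(cfg2, cfg)
  expect_identical(generate_trees(cfg2), generate_trees(cfg))
})
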