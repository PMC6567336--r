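test_that("leaf-count sampler reproduces the four target moments after discretisation", {
  cfg <- generator_config()
  n <- sample_leaf_counts(cfg, 20000, seed = 42)
  expect_true(all(n >= 1))
  expect_type(n, "integer")
  s <- moment_summary(n)
  expect_lt(abs(s$mean - 22.0) / 22.0, 0.05)
  expect_lt(abs(s$sd_corrected - 3.7) / 3.7, 0.05)
  expect_lt(abs(s$skewness - (-1.3)) / 1.3, 0.05)
  expect_lt(abs(s$kurtosis - 5.6) / 5.6, 0.05)
})

test_that("vanishing spread collapses all counts onto the rounded mean", {
  cfg <- generator_config(count_sd = 1e-6)
  n <- sample_leaf_counts(cfg, 500, seed = 1)
  expect_true(all(n == 22L))
})

test_that("normal moment targets give near-zero sample skewness", {
  cfg <- generator_config(count_skewness = 0, count_kurtosis = 3)
  n <- sample_leaf_counts(cfg, 20000, seed = 42)
  expect_lt(abs(moment_summary(n)$skewness), 0.1)
})

test_that("infeasible moment combinations are rejected before sampling", {
  expect_error(generator_config(count_skewness = 2, count_kurtosis = 4),
               "infeasible")
})

test_that("identical configuration and seed give bit-identical populations", {
  cfg <- generator_config()
  a <- suppressWarnings(generate_colonies(cfg, 300, seed = 7))
  b <- suppressWarnings(generate_colonies(cfg, 300, seed = 7))
  expect_identical(a, b)
  expect_identical(
    apply_trawl_selectivity(a, cfg, seed = 3),
    apply_trawl_selectivity(b, cfg, seed = 3)
  )
  expect_identical(
    simulate_rov_counts(a, cfg, seed = 5),
    simulate_rov_counts(b, cfg, seed = 5)
  )
})

test_that("generated colonies satisfy every table invariant", {
  cfg <- generator_config()
  colonies <- suppressWarnings(generate_colonies(cfg, 1000, seed = 11))
  expect_silent(validate_colony_table(colonies))
  expect_true(all(colonies$peduncle_length_mm < colonies$total_length_mm))
  expect_true(all(colonies$fresh_weight_g >= 0.01))
  has_dry <- !is.na(colonies$dry_weight_g)
  expect_true(all(colonies$dry_weight_g[has_dry] <
                    colonies$fresh_weight_g[has_dry]))
})

test_that("noise-free generation lies exactly on the biometric laws", {
  cfg <- generator_config(noise_rachis = 0, noise_total = 0,
                          noise_fresh = 0, noise_dry = 0,
                          asymmetry_prob = 0)
  colonies <- suppressWarnings(generate_colonies(cfg, 200, seed = 3))
  n <- leaf_count_for_size(colonies)
  expect_identical(colonies$leaves_left, colonies$leaves_right)
  expect_equal(rachis_length(colonies), 2.6 * n - 1.1, tolerance = 1e-12)
  expect_equal(colonies$total_length_mm, 5.8 * n + 8.1, tolerance = 1e-12)
  # a colony with 22 leaves sits at the published sizes
  if (any(n == 22)) {
    i <- which(n == 22)[1]
    expect_equal(rachis_length(colonies)[i], 56.1, tolerance = 1e-9)
    expect_equal(colonies$total_length_mm[i], 135.7, tolerance = 1e-9)
  }
})

test_that("asymmetry controls whether side counts can differ", {
  cfg0 <- generator_config(asymmetry_prob = 0)
  colonies <- suppressWarnings(generate_colonies(cfg0, 300, seed = 9))
  expect_identical(colonies$leaves_left, colonies$leaves_right)

  cfg1 <- generator_config(asymmetry_prob = 1, asymmetry_max_loss = 3)
  colonies <- suppressWarnings(generate_colonies(cfg1, 300, seed = 9))
  d <- abs(colonies$leaves_left - colonies$leaves_right)
  expect_true(all(d >= 1 & d <= 3))
})

test_that("noise-free refit recovers the generating coefficients", {
  cfg <- generator_config(noise_rachis = 0, noise_total = 0,
                          noise_fresh = 0, noise_dry = 0)
  colonies <- suppressWarnings(generate_colonies(cfg, 168, seed = 21))
  fit <- fit_linear_size(leaf_count_for_size(colonies),
                         rachis_length(colonies))
  expect_lt(abs(fit$slope - 2.6) / 2.6, 1e-6)
  expect_lt(abs(fit$intercept - (-1.1)) / 1.1, 1e-6)
})

test_that("refit slope on noisy data falls within its own confidence interval", {
  cfg <- generator_config()
  colonies <- suppressWarnings(generate_colonies(cfg, 168, seed = 33))
  fit <- fit_linear_size(leaf_count_for_size(colonies),
                         rachis_length(colonies))
  expect_gt(2.6, fit$slope - 1.96 * fit$slope_se)
  expect_lt(2.6, fit$slope + 1.96 * fit$slope_se)
})

test_that("steep selectivity reduces to a step function at L50", {
  cfg <- generator_config(trawl_l50 = 15, trawl_steepness = 1e8)
  counts <- c(10L, 12L, 14L, 16L, 18L, 25L)
  colonies <- make_colonies(counts)
  kept <- apply_trawl_selectivity(colonies, cfg, seed = 2)
  expect_identical(kept$leaves_left, counts[counts > 15])

  all_cfg <- generator_config(trawl_l50 = 0, trawl_steepness = 1e8)
  expect_identical(nrow(apply_trawl_selectivity(colonies, all_cfg, seed = 2)),
                   nrow(colonies))
})

test_that("selectivity enriches the retained sample in large colonies", {
  cfg <- generator_config()
  colonies <- suppressWarnings(generate_colonies(cfg, 400, seed = 12))
  n_all <- mean(leaf_count_for_size(colonies))
  bigger <- vapply(1:100, function(s) {
    kept <- apply_trawl_selectivity(colonies, cfg, seed = s)
    mean(leaf_count_for_size(kept)) >= n_all
  }, logical(1))
  expect_true(all(bigger))
})

test_that("ROV counting errors behave as terminal-leaf Bernoulli misses", {
  colonies <- make_colonies(c(20L, 22L, 4L))

  cfg0 <- generator_config(rov_edge_miss_prob = 0)
  obs <- simulate_rov_counts(colonies, cfg0, seed = 1)
  expect_identical(obs$leaf_count, c(20L, 22L, 4L))

  cfg1 <- generator_config(rov_edge_miss_prob = 1)
  obs <- simulate_rov_counts(colonies, cfg1, seed = 1)
  expect_identical(obs$leaf_count, c(18L, 20L, 2L))
})

test_that("default ROV miss rate sets the ROV mean near 90% of the trawl-sample mean", {
  cfg <- generator_config()
  colonies <- suppressWarnings(generate_colonies(cfg, 6000, seed = 19))
  trawl_mean <- mean(leaf_count_for_size(
    apply_trawl_selectivity(colonies, cfg)
  ))
  rov_mean <- mean(simulate_rov_counts(colonies, cfg)$leaf_count)
  expect_gt(rov_mean / trawl_mean, 0.87)
  expect_lt(rov_mean / trawl_mean, 0.94)
})
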