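test_that("rachis length is the total minus the peduncle, conserving totals", {
  colonies <- make_colonies(c(22L, 30L, 18L))
  lr <- rachis_length(colonies)
  expect_equal(lr + colonies$peduncle_length_mm, colonies$total_length_mm)
  expect_true(all(lr > 0))

  one <- validate_colony_table(data.frame(
    colony_id = "x", leaves_left = 22L, leaves_right = 22L,
    total_length_mm = 135.7, peduncle_length_mm = 79.6,
    fresh_weight_g = 2.4, dry_weight_g = NA_real_
  ))
  expect_equal(rachis_length(one), 56.1)
})

test_that("size models use the max-side count and weight models the mean-side count", {
  colonies <- make_colonies(c(20L, 20L, 5L, 21L), c(18L, 20L, 0L, 20L))
  expect_identical(leaf_count_for_size(colonies), c(20L, 20L, 5L, 21L))
  expect_equal(leaf_count_for_weight(colonies), c(19, 20, 2.5, 20.5))
})

test_that("RMS relative error matches its definition and a loop oracle", {
  expect_equal(rms_relative_error(c(2, 3), c(2, 3)), 0)
  expect_equal(rms_relative_error(1.1, 1.0), 0.1)
  expect_error(rms_relative_error(c(1, 2), c(1, 0)), "0")
  expect_error(rms_relative_error(1:3, 1:2), "equal length")

  set.seed(5)
  for (rep in 1:5) {
    obs <- runif(10, 0.5, 5)
    pred <- obs * (1 + rnorm(10, 0, 0.2))
    expect_equal(rms_relative_error(pred, obs),
                 oracle_rms_relative_error(pred, obs),
                 tolerance = 1e-12)
  }
})

test_that("linear size fit recovers exact lines and matches normal equations", {
  n <- c(10, 14, 18, 22, 26, 30)
  fit <- fit_linear_size(n, 2.6 * n - 1.1)
  expect_equal(fit$slope, 2.6, tolerance = 1e-10)
  expect_equal(fit$intercept, -1.1, tolerance = 1e-10)
  expect_equal(fit$rms_relative_error, 0, tolerance = 1e-10)
  expect_equal(fit$correlation, 1, tolerance = 1e-12)

  fit <- fit_linear_size(c(1, 2, 3), c(1, 2, 3))
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)

  set.seed(8)
  x <- c(12, 15, 19, 24, 28)
  y <- 2.6 * x - 1.1 + rnorm(5, 0, 3)
  fit <- fit_linear_size(x, y)
  o <- oracle_ols(x, y)
  expect_equal(fit$slope, unname(o["slope"]), tolerance = 1e-10)
  expect_equal(fit$intercept, unname(o["intercept"]), tolerance = 1e-10)

  expect_error(fit_linear_size(c(5, 5, 5), c(1, 2, 3)), "identical")
  expect_error(fit_linear_size(c(1, 2), c(1, 2)), "at least 3")
})

test_that("length predictions evaluate the published model forms", {
  rachis <- linear_size_model(2.6, -1.1)
  total <- linear_size_model(5.8, 8.1)
  expect_equal(predict_length(rachis, 22), 56.1)
  expect_equal(predict_length(total, 0), 8.1)
  expect_equal(predict_length(total, 22), 135.7)
  expect_warning(predict_length(rachis, 0.1), "negative")
})

test_that("cubic weight fit recovers exact cubics and rejects degeneracy", {
  n <- c(16, 18, 20, 22, 24, 26, 28)
  w <- -0.0013 * n^3 + 0.076 * n^2 - 1.17 * n + 5.342
  fit <- fit_cubic_weight(n, w)
  expect_equal(fit$c3, -0.0013, tolerance = 1e-8)
  expect_equal(fit$c2, 0.076, tolerance = 1e-8)
  expect_equal(fit$c1, -1.17, tolerance = 1e-8)
  expect_equal(fit$c0, 5.342, tolerance = 1e-8)
  expect_equal(fit$rms_relative_error, 0, tolerance = 1e-8)

  expect_error(fit_cubic_weight(c(1, 1, 2, 2, 3), 1:5), "4 distinct")
  expect_error(fit_cubic_weight(1:4, 1:4), "at least 5")
})

test_that("cubic weight predictions respect the validity bound and positivity", {
  model <- default_cubic()
  expect_true(is.na(predict_fresh_weight(model, 10)))
  expect_true(is.na(predict_fresh_weight(model, 15)))
  expect_equal(predict_fresh_weight(model, 22), 2.5436, tolerance = 1e-12)
  # strictly increasing up to the cubic's interior maximum near n = 28.4
  preds <- predict_fresh_weight(model, 16:28)
  expect_true(all(diff(preds) > 0))
  expect_gt(predict_fresh_weight(model, 28), predict_fresh_weight(model, 29))

  falling <- cubic_weight_model(0, 0, -1, 10)
  expect_warning(w <- predict_fresh_weight(falling, 20), "clamped")
  expect_equal(w, 0)
})

test_that("weight surface fit reproduces published coefficients' predictions and nests the cubic", {
  surf <- surface_weight_model(2.28e-4, -0.023, 0.826, 0.039, -9.182)
  expect_equal(predict_surface_weight(surf, 22, 56.1), 2.473644,
               tolerance = 1e-12)

  set.seed(14)
  n <- rep(c(16, 19, 22, 25, 28), each = 4)
  lr <- 2.6 * n - 1.1 + rnorm(length(n), 0, 6)  # independent length variation
  w <- 2.28e-4 * n^3 - 0.023 * n^2 + 0.826 * n + 0.039 * lr - 9.182
  fit <- fit_weight_surface(n, lr, w)
  expect_equal(fit$a3, 2.28e-4, tolerance = 1e-6)
  expect_equal(fit$b1, 0.039, tolerance = 1e-6)
  expect_equal(fit$rms_relative_error, 0, tolerance = 1e-7)

  # collinear rachis (exactly linear in n) must be diagnosed
  expect_error(fit_weight_surface(n, 2.6 * n - 1.1, w), "rank deficient")

  # the surface cannot fit worse than the nested cubic in residual SS
  wn <- w + rnorm(length(n), 0, 0.3)
  cub <- fit_cubic_weight(n, wn)
  pred_cub <- pracma::polyval(c(cub$c3, cub$c2, cub$c1, cub$c0), n)
  surf_fit <- fit_weight_surface(n, lr, wn)
  pred_surf <- predict_surface_weight(surf_fit, n, lr)
  expect_lte(sum((wn - pred_surf)^2), sum((wn - pred_cub)^2) + 1e-9)
})

test_that("dry weight fit recovers exact cubics and published predictions", {
  dry_model <- dry_weight_model(0.062, -0.412, 1.134, -0.416)
  expect_equal(predict_dry_weight(dry_model, 2.39), 0.787293778,
               tolerance = 1e-9)

  f <- c(0.6, 1.1, 1.7, 2.4, 3.2, 4.1, 5.0)
  d <- 0.062 * f^3 - 0.412 * f^2 + 1.134 * f - 0.416
  fit <- fit_dry_weight(f, d)
  expect_equal(fit$d3, 0.062, tolerance = 1e-7)
  expect_equal(fit$d0, -0.416, tolerance = 1e-7)
  expect_equal(fit$rms_relative_error, 0, tolerance = 1e-7)

  expect_error(fit_dry_weight(c(1, 1, 1, 2, 2), 1:5), "4 distinct")
})

test_that("each fit is the least-squares minimiser under coefficient perturbation", {
  set.seed(23)
  n <- runif(40, 16, 30)
  w <- (-0.0013 * n^3 + 0.076 * n^2 - 1.17 * n + 5.342) * exp(rnorm(40, 0, 0.3))
  fit <- fit_cubic_weight(n, w)
  co <- c(fit$c3, fit$c2, fit$c1, fit$c0)
  sse <- function(p) sum((w - pracma::polyval(p, n))^2)
  base <- sse(co)
  for (i in 1:4) {
    for (f in c(0.99, 1.01)) {
      p <- co
      p[i] <- p[i] * f
      expect_gte(sse(p), base)
    }
  }
})

test_that("the stored error metric equals the metric recomputed on training data", {
  set.seed(31)
  n <- runif(60, 5, 30)
  lr <- (2.6 * n - 1.1) * (1 + rnorm(60, 0, 0.118))
  fit <- fit_linear_size(n, lr)
  expect_equal(fit$rms_relative_error,
               rms_relative_error(fit$slope * n + fit$intercept, lr),
               tolerance = 1e-12)

  w <- pmax(0.05, (-0.0013 * n^3 + 0.076 * n^2 - 1.17 * n + 5.342)) *
    exp(rnorm(60, 0, 0.3))
  cub <- fit_cubic_weight(n, w)
  valid <- n > 15
  expect_equal(
    cub$rms_relative_error,
    rms_relative_error(
      pracma::polyval(c(cub$c3, cub$c2, cub$c1, cub$c0), n[valid]), w[valid]
    ),
    tolerance = 1e-12
  )
})
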