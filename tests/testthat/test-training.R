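test_that("learning-rate schedule follows integer-division decay", {
  cfg <- train_config()
  expect_equal(decayed_learning_rate(cfg, 0), 1e-4)
  expect_equal(decayed_learning_rate(cfg, 19), 1e-4)
  expect_equal(decayed_learning_rate(cfg, 20), 1e-5)
  expect_equal(decayed_learning_rate(cfg, 40), 1e-6)
  rates <- vapply(0:100, function(s) decayed_learning_rate(cfg, s),
                  numeric(1))
  expect_true(all(diff(rates) <= 0))
  expect_error(decayed_learning_rate(cfg, -1), "global_step")
  # the alternative 0.9-factor reading stays available through config
  cfg9 <- train_config(decay_rate = 0.9)
  expect_equal(decayed_learning_rate(cfg9, 20), 9e-5)
})

test_that("mse loss matches the half-sum-of-squares form", {
  expect_equal(mse_loss(c(0, 0), c(1, 1)), 1)
  expect_equal(mse_loss(matrix(1:4, 2), matrix(1:4, 2)), 0)
  set.seed(12)
  p <- matrix(rnorm(20), 4); y <- matrix(rnorm(20), 4)
  expect_equal(mse_loss(y + 2 * (p - y), y), 4 * mse_loss(p, y))
  expect_equal(mse_loss(p, y, m = 4), mse_loss(p, y) / 4)
  expect_error(mse_loss(matrix(0, 2, 2), matrix(0, 2, 3)), "shape")
})

test_that("Nadam matches an independent reference implementation", {
  # reference: textbook Nadam recursion on a plain numeric vector
  ref_nadam <- function(theta, grads, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
    m <- v <- theta * 0
    for (t in seq_along(grads)) {
      g <- grads[[t]]
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g^2
      mhat <- m / (1 - b1^t)
      vhat <- v / (1 - b2^t)
      theta <- theta - lr * (b1 * mhat + (1 - b1) * g / (1 - b1^t)) /
        (sqrt(vhat) + eps)
    }
    theta
  }
  set.seed(13)
  theta0 <- rnorm(5)
  grads <- lapply(1:7, function(i) rnorm(5))
  theta <- theta0; st <- NULL
  for (t in 1:7) {
    r <- fanrec:::nadam_step(theta, grads[[t]], st, 0.01, 0.9, 0.999, 1e-8, t)
    theta <- r$theta; st <- r$state
  }
  expect_equal(theta, ref_nadam(theta0, grads, 0.01), tolerance = 1e-12)
})

test_that("corrupted sinograms have full shape and honest limits", {
  g <- test_geom()
  # complete input round-trips within a percent on a smooth phantom
  smooth <- ellipse_phantom(data.frame(cx = 3, cy = -4, a = 20, b = 15,
                                       theta = 0.4, mu = 0.7), test_grid)
  s <- analytic_fan_projection(smooth, g)
  co <- make_corrupted(s, g, out_size = test_grid)
  expect_identical(co$kind, "corrupted")
  expect_identical(dim(co$values), c(g$n_views, g$n_channels))
  expect_lt(rel_rms(co$values, s$values), 0.05)

  sp <- subsample_views(s, 8)
  co_sp <- make_corrupted(sp, g, out_size = test_grid)
  expect_identical(dim(co_sp$values), c(g$n_views, g$n_channels))

  zero <- sinogram(matrix(0, 12, g$n_channels), g,
                   angles = view_angles(g)[seq(1, 96, by = 8)],
                   kind = "sparse", factor = 8L,
                   view_index = seq(1, 96, by = 8))
  expect_equal(make_corrupted(zero, g, out_size = test_grid)$values,
               matrix(0, g$n_views, g$n_channels))
})

test_that("training bookkeeping: history, schedule, reproducibility", {
  g <- scaled_geometry(test_grid, n_views = 64)
  p <- cached("cross_phantom", generate_random_phantom(42, grid_size = test_grid))
  s <- analytic_fan_projection(p, g)
  pair <- training_pair(subsample_views(s, 8), s, out_size = test_grid)
  net <- build_unet(c(64, g$n_channels), 4, 2)
  cfg <- train_config(outer_iterations = 41, decay_steps = 20, seed = 4)
  fit <- train(list(pair), net, cfg)
  expect_identical(nrow(fit$history), 41L)
  expect_equal(fit$history$learning_rate[1], 1e-4)
  expect_equal(fit$history$learning_rate[21], 1e-5)
  # epoch with 0-based index 40 runs at initial * decay^2
  expect_equal(fit$history$learning_rate[41], 1e-6)
  expect_true(all(is.finite(fit$history$loss)))

  cfg2 <- train_config(outer_iterations = 3, seed = 4)
  f1 <- train(list(pair), build_unet(c(64, g$n_channels), 4, 2), cfg2)
  f2 <- train(list(pair), build_unet(c(64, g$n_channels), 4, 2), cfg2)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$net$params, f2$net$params)

  broken <- initialize_parameters(build_unet(c(64, g$n_channels), 4, 2), 1)
  broken$params[[2]]$W[1] <- Inf
  expect_error(train(list(pair), broken, cfg2), "non-finite loss at epoch 1")
  expect_error(train(list(), net, cfg2), "at least one")
})

test_that("a single pair can be overfit far below its initial loss", {
  g <- scaled_geometry(test_grid, n_views = 64)
  p <- generate_random_phantom(5, grid_size = test_grid)
  s <- analytic_fan_projection(p, g)
  pair <- training_pair(subsample_views(s, 8), s, out_size = test_grid)
  net <- build_unet(c(64, g$n_channels), test_base_channels, 2)
  # single-stage schedule: the published initial rate held for 200 epochs
  cfg <- train_config(initial_learning_rate = 1e-4, decay_steps = 200,
                      outer_iterations = 200, seed = 3)
  fit <- train(list(pair), net, cfg)
  expect_lt(fit$history$loss[200], 0.10 * fit$history$loss[1])
})
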