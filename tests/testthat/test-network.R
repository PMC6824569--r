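test_that("normalization matches the closed form and inverts exactly", {
  n <- normalize_grid(matrix(1:4, 2))
  # population standard deviation sqrt(1.25)
  expect_equal(as.numeric(n$values), c(-1.3416408, -0.4472136, 0.4472136,
                                       1.3416408), tolerance = 1e-6)
  expect_equal(mean(n$values), 0, tolerance = 1e-10)
  expect_equal(sqrt(mean(n$values^2)), 1, tolerance = 1e-10)

  set.seed(8)
  x <- matrix(rnorm(60, 5, 3), 6)
  expect_equal(normalize_grid(3 * x + 11)$values, normalize_grid(x)$values,
               tolerance = 1e-9)
  expect_equal(denormalize_grid(normalize_grid(x)), x, tolerance = 1e-9)

  z <- normalize_grid(x)
  z$values <- z$values * 0
  expect_equal(denormalize_grid(z), matrix(z$source_mean, 6, 10))
  zz <- normalize_grid(x)
  expect_equal(denormalize_grid(zz, source_sd = 2 * zz$source_sd) -
                 zz$source_mean,
               2 * (denormalize_grid(zz) - zz$source_mean),
               tolerance = 1e-9)

  expect_error(normalize_grid(matrix(3, 4, 4)), "constant")
  expect_error(normalize_grid(numeric(0)), "empty")
})

test_that("small-scale network shapes follow the ceil-halving scheme", {
  net <- build_unet(c(64, 64), base_channels = 8, depth = 1)
  expect_length(net$nodes, 12)          # 7 + 5 * depth
  ls <- layer_spec(net)
  shapes <- unique(paste(ls$out_h, ls$out_w, ls$out_c))
  expect_true(all(c("64 64 8", "32 32 16", "64 64 1") %in% shapes))

  # odd sizes: ceil on the way down, exact restoration on the way up
  net2 <- build_unet(c(45, 183), base_channels = 4, depth = 2)
  ls2 <- layer_spec(net2)
  down1 <- ls2[ls2$stride_h %in% 2 & ls2$kind == "Conv", ]
  expect_equal(down1$out_h, c(23, 12))
  expect_equal(down1$out_w, c(92, 46))
  up <- ls2[ls2$kind == "ConvTranspose", ]
  expect_equal(up$out_h, c(23, 45))
  expect_equal(up$out_w, c(92, 183))

  expect_error(build_unet(c(8, 8), 4, 4), "too small")
  expect_error(build_unet(c(64, 64), 0, 1), "base_channels")
})

test_that("downsample modes halve axes and agree where they should", {
  m <- matrix(rnorm(720 * 731), 720, 731)
  expect_equal(dim(downsample(m)), c(360, 366))
  expect_equal(downsample(m, rep(0.25, 4), "strided_conv"),
               downsample(m, mode = "mean_pool"), tolerance = 1e-14)
  w <- matrix(c(1, 3, 5, 2), 2)      # window rows (1 5 / 3 2)
  expect_equal(downsample(w, mode = "max_pool"), matrix(5, 1, 1))
  expect_equal(downsample(w, c(1, 0, 0, 0), "strided_conv"), matrix(1, 1, 1))
  # channel dimension is preserved for arrays
  a <- array(rnorm(9 * 7 * 3), c(9, 7, 3))
  expect_equal(dim(downsample(a, mode = "max_pool")), c(5, 4, 3))
})

test_that("initialization is seeded and follows the fan-in/out scale", {
  net <- build_unet(c(96, 93), 16, 1)
  n1 <- initialize_parameters(net, 5)
  n2 <- initialize_parameters(net, 5)
  expect_identical(n1$params, n2$params)
  n3 <- initialize_parameters(net, 6)
  expect_false(identical(n1$params, n3$params))

  # node 3: 3x3 conv 16 -> 16, n_in = n_out = 144 -> sd = sqrt(2/288)
  W <- n1$params[[3]]$W
  expect_equal(sd(W), sqrt(2 / 288), tolerance = 0.02)
  expect_lt(abs(mean(W)), 3 * sd(W) / sqrt(length(W)))
  expect_equal(n1$params[[3]]$b, rep(0, 16))
  expect_equal(n1$params[[3]]$gamma, rep(1, 16))
})

test_that("residual identity: zero final conv returns the normalized input", {
  net <- initialize_parameters(build_unet(c(32, 33), 4, 1), 2)
  final_conv <- length(net$nodes) - 2L
  expect_identical(net$nodes[[final_conv]]$kind, "conv")
  expect_identical(net$nodes[[final_conv]]$out_shape[3], 1L)
  net$params[[final_conv]]$W[] <- 0
  net$params[[final_conv]]$b[] <- 0
  set.seed(10)
  x <- normalize_grid(matrix(rnorm(32 * 33), 32))
  out <- forward_pass(net, x)
  expect_equal(out$values, x$values, tolerance = 1e-10)
  expect_identical(out$source_mean, x$source_mean)
})

test_that("forward pass shape contract and determinism", {
  net <- initialize_parameters(build_unet(c(32, 33), 4, 2), 3)
  set.seed(11)
  x <- normalize_grid(matrix(rnorm(32 * 33), 32))
  o1 <- forward_pass(net, x)
  o2 <- forward_pass(net, x)
  expect_identical(o1$values, o2$values)
  expect_equal(dim(o1$values), c(32, 33))
  expect_true(all(is.finite(o1$values)))
  # output of the final normalization layer is standardized
  expect_equal(mean(o1$values), 0, tolerance = 1e-10)
  expect_equal(sqrt(mean(o1$values^2)), 1, tolerance = 1e-10)
  bad <- normalize_grid(matrix(rnorm(33 * 32), 33))
  expect_error(forward_pass(net, bad), "does not match")
  expect_error(forward_pass(build_unet(c(32, 33), 4, 1), x), "parameters")
})

test_that("analytic gradients match central finite differences", {
  for (mode in c("strided_conv", "max_pool", "mean_pool"))
    expect_lt(max_grad_error(mode), 1e-4)
})
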