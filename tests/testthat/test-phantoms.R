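test_that("generator is deterministic and honours the count range", {
  p1 <- generate_random_phantom(7, grid_size = 128)
  p2 <- generate_random_phantom(7, grid_size = 128)
  expect_identical(p1, p2)

  p3 <- generate_random_phantom(8, grid_size = 128)
  expect_false(identical(p1$ellipses, p3$ellipses))

  single <- generate_random_phantom(3, n_ellipses_min = 1,
                                    n_ellipses_max = 1, grid_size = 64)
  expect_identical(nrow(single$ellipses), 1L)

  counts <- vapply(seq_len(1000), function(i)
    nrow(generate_random_phantom(i, grid_size = 64)$ellipses), integer(1))
  expect_true(all(counts >= 10 & counts <= 40))
  expect_gte(mean(counts), 10)
  expect_lte(mean(counts), 40)
  expect_gt(length(unique(counts)), 10)  # actually spans the range
})

test_that("generator arguments are validated", {
  expect_error(generate_random_phantom(1, n_ellipses_min = 0), "n_ellipses")
  expect_error(generate_random_phantom(1, n_ellipses_min = 5,
                                       n_ellipses_max = 4), "n_ellipses")
  expect_error(generate_random_phantom(1, grid_size = 8), "grid_size")
})

test_that("every generated ellipse lies inside the support disk", {
  for (seed in 1:25) {
    p <- generate_random_phantom(seed, grid_size = 64)
    e <- p$ellipses
    ext <- sqrt(e$cx^2 + e$cy^2) + pmax(e$a, e$b)
    expect_true(all(ext <= 32 + 1e-9))
    expect_true(all(e$a > 0 & e$b > 0))
    expect_true(all(e$mu > 0 & e$mu <= 1))
  }
  expect_error(
    ellipse_phantom(data.frame(cx = 30, cy = 0, a = 10, b = 5,
                               theta = 0, mu = 1), 64),
    "support disk")
})

test_that("rasterization is additive and recovers the analytic area", {
  empty <- ellipse_phantom(data.frame(), 64)
  expect_equal(rasterize(empty)$values, matrix(0, 64, 64))

  one <- ellipse_phantom(data.frame(cx = 3, cy = -5, a = 50, b = 30,
                                    theta = 0.7, mu = 1), 256)
  img <- rasterize(one)$values
  expect_equal(sum(img), pi * 50 * 30, tolerance = 0.01)

  two <- ellipse_phantom(one$ellipses[c(1, 1), ], 256)
  expect_equal(rasterize(two)$values, 2 * img)
})

test_that("analytic projection matches closed-form chords", {
  g <- test_geom()
  empty <- ellipse_phantom(data.frame(), test_grid)
  expect_equal(analytic_fan_projection(empty, g)$values,
               matrix(0, g$n_views, g$n_channels))

  disk <- ellipse_phantom(data.frame(cx = 0, cy = 0, a = 20, b = 20,
                                     theta = 0, mu = 0.5), test_grid)
  sino <- analytic_fan_projection(disk, g)
  centre <- (g$n_channels + 1) / 2
  expect_equal(sino$values[, centre], rep(2 * 20 * 0.5, g$n_views),
               tolerance = 1e-12)
})

test_that("analytic projection is linear and rotation-consistent", {
  g <- test_geom()
  p <- generate_random_phantom(21, grid_size = test_grid)
  e <- p$ellipses
  half <- ellipse_phantom(e[1:5, ], test_grid)
  rest <- ellipse_phantom(e[-(1:5), ], test_grid)
  expect_equal(analytic_fan_projection(p, g)$values,
               analytic_fan_projection(half, g)$values +
                 analytic_fan_projection(rest, g)$values,
               tolerance = 1e-12)

  # rotating the phantom by one view step shifts the sinogram by one row
  dphi <- g$angular_range / g$n_views
  rot <- within(e, {
    ang <- atan2(cy, cx) + dphi
    r <- sqrt(cx^2 + cy^2)
    cx <- r * cos(ang); cy <- r * sin(ang)
    theta <- theta + dphi
  })
  s0 <- analytic_fan_projection(p, g)$values
  s1 <- analytic_fan_projection(ellipse_phantom(rot[names(e)], test_grid),
                                g)$values
  shifted <- rbind(s0[g$n_views, , drop = FALSE],
                   s0[-g$n_views, , drop = FALSE])
  expect_equal(s1, shifted, tolerance = 1e-9)
})

test_that("raster and analytic projectors agree (cross-oracle)", {
  g <- test_geom()
  p <- cached("cross_phantom", generate_random_phantom(42, grid_size = test_grid))
  a <- analytic_fan_projection(p, g)$values
  r <- forward_project(rasterize(p), g)$values
  # raster pixelation dominates at this small grid (~2%); the 1% contract
  # is checked at the full 512 grid in the acceptance suite
  expect_lt(rel_rms(r, a), 0.03)
})

test_that("out-of-field phantoms are rejected with the offending ellipse", {
  g <- fan_geometry(source_distance = 200, n_views = 8, n_channels = 31)
  p <- ellipse_phantom(data.frame(cx = 0, cy = 0, a = 30, b = 30,
                                  theta = 0, mu = 1), 64)
  expect_error(analytic_fan_projection(p, g), "ellipse 1")
})

test_that("phantom JSON round trip preserves the phantom", {
  p <- generate_random_phantom(12, grid_size = 64)
  path <- withr::local_tempfile(fileext = ".json")
  write_phantom(p, path)
  q <- read_phantom(path)
  expect_equal(q$grid_size, p$grid_size)
  expect_equal(q$ellipses, p$ellipses, tolerance = 1e-12)
})
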