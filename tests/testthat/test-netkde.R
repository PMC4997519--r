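test_that("single-event densities match the closed-form Gaussian kernel", {
  # long line so the 600 m bandwidth fits
  ln <- line_net(1500)
  lx <- subdivide_lixels(ln, 20)  # centres at 10, 30, ...

  # event exactly at a lixel centre: lambda = (1/r) / sqrt(2*pi)
  ev <- network_events(npt(1, 10))
  f <- netkde(ln, ev, lixels = lx, bandwidth = 600)
  expect_equal(f$lambda[1], 1 / (600 * sqrt(2 * pi)), tolerance = 1e-12)

  # at network distance exactly r: exp(-1/2) / (r * sqrt(2*pi))
  i600 <- which(lx$centre == 610)
  expect_equal(f$lambda[i600], exp(-0.5) / (600 * sqrt(2 * pi)),
               tolerance = 1e-12)

  # truncation: zero contribution beyond the bandwidth
  i_beyond <- which(lx$centre > 610)
  expect_equal(f$lambda[i_beyond], rep(0, length(i_beyond)))

  # linearity in the weight: doubling B doubles the field
  f2 <- netkde(ln, network_events(npt(1, 10), weight = 2), lixels = lx,
               bandwidth = 600)
  expect_equal(f2$lambda, 2 * f$lambda, tolerance = 1e-12)

  expect_error(netkde(ln, ev, lixels = lx, bandwidth = 0), "bandwidth")
  expect_error(netkde(ln, network_events(npt(5, 1)), lixels = lx,
                      bandwidth = 600), "edge")
})

test_that("weighted field is the weight-scaled superposition of single-event fields", {
  net <- rand_test_net(11)
  lx <- subdivide_lixels(net, 50)
  pts <- sample_csr(net, 6, seed = 3)
  w <- c(5, 1, 0, 2, 10, 1)
  full <- netkde(net, network_events(pts, weight = w), lixels = lx,
                 bandwidth = 300)
  acc <- 0
  for (i in seq_len(6)) {
    single <- netkde(net, network_events(pts[i, , drop = FALSE]), lixels = lx,
                     bandwidth = 300)
    acc <- acc + w[i] * single$lambda
  }
  expect_equal(full$lambda, acc, tolerance = 1e-12)

  # unweighted mode ignores the weights entirely
  unw <- netkde(net, network_events(pts, weight = w), lixels = lx,
                bandwidth = 300, weighted = FALSE)
  ones <- netkde(net, network_events(pts, weight = rep(1, 6)), lixels = lx,
                 bandwidth = 300)
  expect_equal(unw$lambda, ones$lambda)
})

test_that("lixel densities agree with the brute-force shortest-path oracle", {
  for (s in c(21, 22)) {
    net <- rand_test_net(s)
    lx <- subdivide_lixels(net, 60)
    ev <- network_events(sample_csr(net, 15, seed = s),
                         weight = stats::runif(15, 0, 500))
    f <- netkde(net, ev, lixels = lx, bandwidth = 350)
    lam0 <- oracle_netkde(net, ev, lx, 350)
    expect_equal(f$lambda, lam0, tolerance = 1e-9)
  }
})

test_that("density at an isolated event decreases with the bandwidth", {
  ln <- line_net(2000)
  lx <- subdivide_lixels(ln, 20)
  ev <- network_events(npt(1, 10))
  lam_at_event <- vapply(c(100, 300, 600, 1200), function(r)
    netkde(ln, ev, lixels = lx, bandwidth = r)$lambda[1], numeric(1))
  expect_true(all(diff(lam_at_event) < 0))
})

test_that("min-max normalization maps fields onto [0, 1]", {
  f <- structure(list(lixels = data.frame(edge = 1, start = 0:2, end = 1:3,
                                          centre = 0:2 + 0.5, length = 1),
                      lambda = c(2, 4, 6), bandwidth = 600, weighted = TRUE,
                      normalized = FALSE), class = "density_field")
  expect_equal(normalize_field(f)$lambda, c(0, 0.5, 1))

  f$lambda <- c(3, 3, 3)
  expect_equal(normalize_field(f)$lambda, c(0, 0, 0))

  net <- rand_test_net(5)
  g <- netkde(net, network_events(sample_csr(net, 10, seed = 1)),
              bandwidth = 300, cell_size = 50)
  ng <- normalize_field(g)
  expect_equal(max(ng$lambda), 1)
  expect_equal(min(ng$lambda), 0)
})

test_that("rasterization takes length-weighted means over intersecting lixels", {
  ln <- line_net(10)
  lx <- subdivide_lixels(ln, 10)  # one lixel spanning the edge
  f <- structure(list(lixels = lx, lambda = 7, bandwidth = 600,
                      weighted = TRUE, normalized = FALSE),
                 class = "density_field")
  grid <- raster_grid(-5, -5, 20, 1, 1)  # cell covering everything
  r <- rasterize_field(ln, f, grid)
  expect_equal(r$values[1, 1], 7)

  # two equal-length lixels with lambda 1 and 3 in one cell average to 2
  lx2 <- subdivide_lixels(ln, 5)
  f2 <- structure(list(lixels = lx2, lambda = c(1, 3), bandwidth = 600,
                       weighted = TRUE, normalized = FALSE),
                  class = "density_field")
  r2 <- rasterize_field(ln, f2, grid)
  expect_equal(r2$values[1, 1], 2)

  # cells with no network are nodata
  grid2 <- raster_grid(0, -50, 10, 10, 2)
  r3 <- rasterize_field(ln, f2, grid2)
  expect_true(all(is.na(r3$values[1:4, ])))
  expect_true(any(!is.na(r3$values)))

  # splitting across cells conserves length: cell means of a constant field
  sq <- square_ring(100)
  fc <- netkde(sq, network_events(sample_csr(sq, 4, seed = 2)),
               bandwidth = 1000, cell_size = 20)
  fc$lambda <- rep(4.2, length(fc$lambda))
  rc <- rasterize_field(sq, fc, grid_from_network(sq, 30))
  expect_equal(rc$values[!is.na(rc$values)],
               rep(4.2, sum(!is.na(rc$values))), tolerance = 1e-9)
})

test_that("planar KDE matches the bivariate Gaussian closed form", {
  grid <- raster_grid(0, 0, 10, 5, 5)
  cc <- list(x = 45, y = 45)  # centre of cell [5, 5]
  h <- 30
  r <- planar_kde(c(45, 45), 1, h, grid)
  expect_equal(r$values[5, 5], 1 / (2 * pi * h^2), tolerance = 1e-12)

  # truncation beyond the bandwidth
  expect_equal(r$values[1, 1], 0)  # cell centre (5,5) is ~56 m away > 30

  # two identical points behave as one point of weight 2
  r2 <- planar_kde(rbind(c(45, 45), c(45, 45)), 1, h, grid)
  expect_equal(r2$values, 2 * r$values, tolerance = 1e-12)
  r3 <- planar_kde(c(45, 45), 2, h, grid)
  expect_equal(r2$values, r3$values)
})
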