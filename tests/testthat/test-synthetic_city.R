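test_that("grid networks have the expected lattice structure", {
  g <- make_grid_network(3, 3, 100)
  expect_equal(nrow(g$nodes), 9L)
  expect_equal(nrow(g$edges), 12L)
  expect_equal(network_length(g), 1200)

  g2 <- make_grid_network(2, 2, 50)
  expect_equal(nrow(g2$nodes), 4L)
  expect_equal(nrow(g2$edges), 4L)
  expect_equal(network_length(g2), 200)

  g3 <- make_grid_network(2, 3, 100)
  expect_equal(nrow(g3$nodes), 6L)
  expect_equal(nrow(g3$edges), 7L)

  # perturbed grid keeps the topology but changes edge lengths
  gj <- make_grid_network(3, 3, 100, jitter = 0.2, seed = 1)
  expect_equal(nrow(gj$edges), 12L)
  expect_gt(stats::sd(gj$edges$length), 0)
})

test_that("CSR sampler is length-uniform over edges", {
  net <- make_grid_network(3, 4, 100, jitter = 0.3, seed = 9)
  expect_equal(nrow(sample_csr(net, 0)), 0L)

  p <- sample_csr(net, 50, seed = 1)
  expect_equal(nrow(p), 50L)
  expect_true(all(p$offset >= 0 & p$offset <= net$edges$length[p$edge]))

  # edge-choice frequencies proportional to edge length (chi-square GOF)
  big <- sample_csr(net, 10000, seed = 42)
  obs <- tabulate(big$edge, nbins = nrow(net$edges))
  gof <- stats::chisq.test(obs, p = net$edges$length / net$total_length)
  expect_gt(gof$p.value, 0.01)

  # reproducible under seed
  expect_identical(sample_csr(net, 20, seed = 5), sample_csr(net, 20, seed = 5))
})

test_that("clustered sampler concentrates points around parents", {
  net <- make_grid_network(5, 5, 100)
  cl <- sample_clustered(net, 5, 10, 50, seed = 2)
  expect_equal(nrow(cl), 50L)
  expect_true(all(cl$offset >= 0 & cl$offset <= net$edges$length[cl$edge]))

  # scale -> 0 limit: children collocated with parents (5 distinct sites)
  tiny <- sample_clustered(net, 5, 4, 1e-9, seed = 3)
  xy <- point_coords(net, tiny)
  expect_equal(nrow(unique(round(xy, 3))), 5L)

  # mean nearest-neighbour distance below CSR's across seeds
  mean_nn <- function(pts) {
    D <- network_distance(net, pts, pts)
    diag(D) <- Inf
    mean(apply(D, 1, min))
  }
  nn_cl <- vapply(1:20, function(s)
    mean_nn(sample_clustered(net, 5, 10, 50, seed = s)), numeric(1))
  nn_csr <- vapply(1:20, function(s)
    mean_nn(sample_csr(net, 50, seed = s)), numeric(1))
  expect_lt(mean(nn_cl), mean(nn_csr))
})

test_that("regular sampler is deterministic with guaranteed separation", {
  sq <- square_ring(100)
  r4 <- sample_regular(sq, 100)
  expect_equal(nrow(r4), 4L)

  # spacing larger than the whole network: a single point
  expect_equal(nrow(sample_regular(sq, 500)), 1L)

  net <- make_grid_network(4, 4, 100)
  rg <- sample_regular(net, 150)
  D <- oracle_point_dists(net, rg)
  diag(D) <- Inf
  expect_gte(min(D), 150 / 2)
  expect_identical(sample_regular(net, 150), rg)
})

test_that("attribute assignment follows the configured frequencies", {
  net <- make_grid_network(5, 5, 100)
  pts <- sample_csr(net, 732, seed = 10)
  ev <- assign_attributes(pts, seed = 11)
  expect_s3_class(ev, "network_events")

  # fifth-class count near its expectation (374 of 732), within 4 binomial sd
  n5 <- sum(ev$strength_class == 5L)
  p5 <- 374 / 732
  expect_lt(abs(n5 - 732 * p5), 4 * sqrt(732 * p5 * (1 - p5)))
  expect_true(all(ev$weight >= 0))
  expect_true(all(ev$ownership %in% c("public", "private")))

  # unit-weight mode: every weight exactly 1
  ev1 <- assign_attributes(pts, attribute_config(unit_weights = TRUE), seed = 1)
  expect_equal(ev1$weight, rep(1, 732))

  # reproducibility
  expect_identical(assign_attributes(pts, seed = 4), assign_attributes(pts, seed = 4))

  expect_error(attribute_config(class_probs = c(0.5, 0.2, 0.1, 0.1, 0.2)),
               "sum to 1")
})

test_that("cross-clustered sampler tracks its anchors", {
  net <- make_grid_network(5, 5, 100)
  anchors <- sample_csr(net, 8, seed = 1)
  x <- sample_cross_clustered(net, anchors, 100, 50, seed = 2)
  expect_equal(nrow(x), 100L)

  # scale -> 0: points collocated with anchors
  x0 <- sample_cross_clustered(net, anchors, 20, 1e-9, seed = 3)
  D0 <- network_distance(net, x0, anchors)
  expect_lt(max(apply(D0, 1, min)), 1e-6)

  # mean distance to nearest anchor increases with the scale
  nn_at_scale <- function(scale) {
    mean(vapply(1:10, function(s) {
      pts <- sample_cross_clustered(net, anchors, 50, scale, seed = s)
      mean(apply(network_distance(net, pts, anchors), 1, min))
    }, numeric(1)))
  }
  expect_lt(nn_at_scale(20), nn_at_scale(150))
  expect_error(sample_cross_clustered(net, network_points(integer(0), numeric(0)),
                                      5, 10), "non-empty")
})

test_that("simulate_city produces a coherent scaled scenario", {
  city <- simulate_city(rows = 6, cols = 6, spacing = 100, n_hospitals = 80,
                        n_pharmacies = 50, hospital_scale = 150,
                        pharmacy_scale = 60, seed = 7)
  expect_equal(n_events(city$hospitals), 80L)
  expect_equal(nrow(city$pharmacies), 50L)
  expect_true(all(city$hospitals$strength_class %in% 1:5))
  lens <- city$net$edges$length[city$pharmacies$edge]
  expect_true(all(city$pharmacies$offset <= lens))
})
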