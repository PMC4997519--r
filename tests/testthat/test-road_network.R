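test_that("network construction: square ring, tolerance merging, connectivity", {
  sq <- square_ring(100)
  expect_equal(nrow(sq$nodes), 4L)
  expect_equal(nrow(sq$edges), 4L)
  expect_equal(network_length(sq), 400)

  # endpoints within tolerance merge into one node
  touching <- road_network(list(seg(c(0, 0), c(10, 0)),
                                seg(c(10, 0.3), c(20, 0))), snap_tol = 0.5)
  expect_equal(nrow(touching$nodes), 3L)
  expect_equal(nrow(touching$edges), 2L)

  expect_error(road_network(list(seg(c(0, 0), c(1, 0)),
                                 seg(c(5, 5), c(6, 5)))),
               "2 connected components")

  # edge lengths equal the geometric length of their polylines
  net <- rand_test_net(7)
  geom_len <- vapply(net$geometry, function(m) sum(sqrt(rowSums(diff(m)^2))),
                     numeric(1))
  expect_equal(net$edges$length, geom_len, tolerance = 1e-6)
})

test_that("load_network reads GeoJSON and CSV and rejects geographic coords", {
  sq <- square_ring(100)
  gj <- tempfile(fileext = ".geojson")
  write_geojson_lines(sq, gj)
  rt <- load_network(gj)
  expect_equal(network_length(rt), 400)
  expect_equal(nrow(rt$nodes), 4L)

  csv <- tempfile(fileext = ".csv")
  writeLines(c("id,wkt", '1,"LINESTRING (0 0, 100 0)"',
               '2,"LINESTRING (100 0, 100 100)"',
               '3,"LINESTRING (100 100, 0 0)"'), csv)
  rt2 <- load_network(csv)
  expect_equal(nrow(rt2$edges), 3L)

  geo <- tempfile(fileext = ".csv")
  writeLines(c("id,wkt", '1,"LINESTRING (118.7 32.0, 118.8 32.1)"',
               '2,"LINESTRING (118.8 32.1, 118.9 32.0)"'), geo)
  expect_error(load_network(geo), "geographic")
  expect_error(load_network("/nonexistent/file.geojson"), "not found")
})

test_that("snapping finds the nearest edge point with deterministic ties", {
  ln <- line_net(3)
  s <- snap_points(ln, c(1, 0.5))
  expect_equal(s$points$edge, 1L)
  expect_equal(s$points$offset, 1.0)
  expect_equal(s$dist, 0.5)

  # endpoint clamp
  s2 <- snap_points(ln, c(-1, 0))
  expect_equal(s2$points$offset, 0.0)
  expect_equal(s2$dist, 1.0)

  # point exactly on a shared node: lowest edge id wins
  sq <- square_ring(100)
  s3 <- snap_points(sq, c(100, 0))  # node shared by edges 1 and 2
  expect_equal(s3$points$edge, 1L)
  expect_equal(s3$points$offset, 100)
  expect_equal(s3$dist, 0)
})

test_that("network distances: same edge, detours and ring symmetry", {
  ln <- line_net(3)
  expect_equal(network_distance(ln, npt(1, 0.5), npt(1, 2.5)), 2.0)

  tr <- tri_345()
  # direct 5 m edge beats the 3+4 detour between nodes B and C
  expect_equal(network_distance(tr, npt(1, 3), npt(3, 5)), 5)

  sq <- square_ring(100)
  # opposite corners of the ring: 200 either way
  expect_equal(network_distance(sq, npt(1, 0), npt(2, 100)), 200)

  # same-edge pair routes around the network when that is shorter: a long
  # wiggly edge with a straight 100 m shortcut between its endpoints
  wig <- seg(c(0, 0), c(50, 200), c(100, 0))
  wig_len <- 2 * sqrt(50^2 + 200^2)
  loop <- road_network(list(wig, seg(c(0, 0), c(100, 0))))
  d <- network_distance(loop, npt(1, 10), npt(1, wig_len - 10))
  expect_equal(d, 10 + 100 + 10)  # beats the 392 m run along the wiggly edge
})

test_that("network_distance agrees with the graph-augmentation oracle and is a metric", {
  for (s in 1:5) {
    net <- rand_test_net(s)
    pts <- sample_csr(net, 12, seed = 100 + s)
    D <- network_distance(net, pts, pts)
    expect_equal(D, oracle_point_dists(net, pts), tolerance = 1e-9)
    expect_equal(diag(D), rep(0, nrow(pts)))
    expect_equal(D, t(D))
    expect_true(all(D >= 0))
    # triangle inequality over all sampled triples
    for (i in seq_len(nrow(pts))) {
      expect_true(all(D[i, ] <= D[i, 1] + D[1, ] + 1e-9))
    }
  }
})

test_that("lixel subdivision partitions each edge into equal cells", {
  ln <- line_net(100)
  lx <- subdivide_lixels(ln, 20)
  expect_equal(nrow(lx), 5L)
  expect_equal(lx$centre, c(10, 30, 50, 70, 90))

  # non-dividing cell size: equal split rule
  ln50 <- line_net(50)
  lx2 <- subdivide_lixels(ln50, 20)
  expect_equal(nrow(lx2), 3L)
  expect_equal(lx2$length, rep(50 / 3, 3))

  sq <- square_ring(100)
  lx3 <- subdivide_lixels(sq, 20)
  expect_equal(nrow(lx3), 20L)
  expect_equal(sum(lx3$length), 400)

  # lixel lengths of each edge sum exactly to the edge length
  net <- rand_test_net(3)
  lx4 <- subdivide_lixels(net, 37)
  sums <- tapply(lx4$length, lx4$edge, sum)
  expect_equal(as.numeric(sums), net$edges$length, tolerance = 1e-9)
  expect_true(all(lx4$length <= 37 + 1e-9))
  expect_error(subdivide_lixels(net, 0), "cell_size")
})
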