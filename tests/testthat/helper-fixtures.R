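# Fixture networks built in code, plus independent oracles used to check
# distances, densities, K-functions and centrality against first
# principles.

seg <- function(...) {
  m <- rbind(...)
  storage.mode(m) <- "double"
  m
}

# closed square ring, four 100 m sides
square_ring <- function(side = 100) {
  road_network(list(seg(c(0, 0), c(side, 0)),
                    seg(c(side, 0), c(side, side)),
                    seg(c(side, side), c(0, side)),
                    seg(c(0, side), c(0, 0))))
}

# one straight edge of the given length along the x axis
line_net <- function(length = 2) {
  road_network(list(seg(c(0, 0), c(length, 0))), check_connected = TRUE)
}

# path graph A - B - C with unit edges
path3_net <- function(step = 1) {
  road_network(list(seg(c(0, 0), c(step, 0)), seg(c(step, 0), c(2 * step, 0))))
}

# 3-4-5 triangle: A=(0,0), B=(3,0), C=(0,4)
tri_345 <- function() {
  road_network(list(seg(c(0, 0), c(3, 0)),
                    seg(c(0, 0), c(0, 4)),
                    seg(c(3, 0), c(0, 4))))
}

# star: centre at origin, leaves at unit distance
star_net <- function(n_leaves = 3) {
  ang <- 2 * pi * seq_len(n_leaves) / n_leaves
  road_network(lapply(ang, function(a) seg(c(0, 0), c(cos(a), sin(a)))))
}

# random connected network: jittered grid with random edge drops
rand_test_net <- function(seed, rows = 4, cols = 5, spacing = 100,
                          jitter = 0.2, drop_frac = 0.25) {
  set.seed(seed)
  base <- make_grid_network(rows, cols, spacing, jitter = jitter, seed = seed)
  segs <- base$geometry
  keep <- rep(TRUE, length(segs))
  for (e in sample(length(segs))) {
    if (stats::runif(1) > drop_frac) next
    trial <- keep
    trial[e] <- FALSE
    g <- road_network(segs[trial], check_connected = FALSE)
    if (igraph::components(g$graph)$no == 1L) keep <- trial
  }
  road_network(segs[keep])
}

# ---- independent distance oracle ------------------------------------------
# All-pairs network distances among on-network points, computed by graph
# augmentation: every point becomes a vertex splitting its edge, then
# single-source shortest paths on the augmented graph. Independent of the
# node-matrix + offset arithmetic used by the package.
oracle_point_dists <- function(net, pts) {
  N <- nrow(net$nodes)
  np <- nrow(pts)
  el <- list()
  wt <- numeric(0)
  for (e in seq_len(nrow(net$edges))) {
    idx <- which(pts$edge == e)
    ord <- idx[order(pts$offset[idx])]
    chain_v <- c(net$edges$from[e], N + ord, net$edges$to[e])
    chain_o <- c(0, pts$offset[ord], net$edges$length[e])
    for (s in seq_len(length(chain_v) - 1L)) {
      el[[length(el) + 1L]] <- c(chain_v[s], chain_v[s + 1L])
      wt <- c(wt, max(0, chain_o[s + 1L] - chain_o[s]))
    }
  }
  g <- igraph::graph_from_edgelist(do.call(rbind, el), directed = FALSE)
  if (igraph::vcount(g) < N + np)
    g <- igraph::add_vertices(g, N + np - igraph::vcount(g))
  igraph::distances(g, v = N + seq_len(np), to = N + seq_len(np), weights = wt)
}

# brute-force NetKDE: double loop over lixel centres and events using the
# oracle distances
oracle_netkde <- function(net, events, lixels, bandwidth) {
  centres <- network_points(lixels$edge, lixels$centre)
  all_pts <- rbind(as.data.frame(centres), as.data.frame(events$location))
  class(all_pts) <- c("network_points", "data.frame")
  D <- oracle_point_dists(net, all_pts)
  nc <- nrow(centres)
  lambda <- numeric(nc)
  for (i in seq_len(nc)) {
    acc <- 0
    for (j in seq_len(nrow(events$location))) {
      d <- D[i, nc + j]
      if (d <= bandwidth)
        acc <- acc + events$weight[j] *
          exp(-d^2 / (2 * bandwidth^2)) / (bandwidth * sqrt(2 * pi))
    }
    lambda[i] <- acc
  }
  lambda
}

# brute-force auto K-function from oracle pairwise distances
oracle_auto_k <- function(net, pts, t_grid) {
  D <- oracle_point_dists(net, pts)
  n <- nrow(pts)
  vapply(t_grid, function(t) {
    cnt <- 0
    for (i in seq_len(n)) for (j in seq_len(n))
      if (i != j && D[i, j] <= t) cnt <- cnt + 1
    net$total_length / (n * (n - 1)) * cnt
  }, numeric(1))
}

oracle_cross_k <- function(net, base, target, t_grid) {
  all_pts <- rbind(as.data.frame(base), as.data.frame(target))
  class(all_pts) <- c("network_points", "data.frame")
  D <- oracle_point_dists(net, all_pts)
  nb <- nrow(base); nt <- nrow(target)
  vapply(t_grid, function(t) {
    cnt <- 0
    for (i in seq_len(nb)) for (j in seq_len(nt))
      if (D[i, nb + j] <= t) cnt <- cnt + 1
    net$total_length / (nb * nt) * cnt
  }, numeric(1))
}

# ---- independent centrality oracle ----------------------------------------
# Hand-rolled Floyd-Warshall distances plus shortest-path counting by
# dynamic programming in order of distance, then the ordered-pair
# betweenness sum with fractional credit for tied paths.
oracle_node_dists <- function(net) {
  N <- nrow(net$nodes)
  D <- matrix(Inf, N, N); diag(D) <- 0
  for (e in seq_len(nrow(net$edges))) {
    u <- net$edges$from[e]; v <- net$edges$to[e]; w <- net$edges$length[e]
    D[u, v] <- min(D[u, v], w); D[v, u] <- min(D[v, u], w)
  }
  for (k in seq_len(N)) for (i in seq_len(N)) for (j in seq_len(N))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracle_betweenness <- function(net, tol = 1e-9) {
  N <- nrow(net$nodes)
  D <- oracle_node_dists(net)
  sigma <- matrix(0, N, N)
  for (j in seq_len(N)) {
    sigma[j, j] <- 1
    for (v in order(D[j, ])) {
      if (v == j) next
      s <- 0
      for (e in seq_len(nrow(net$edges))) {
        u <- NULL
        if (net$edges$from[e] == v) u <- net$edges$to[e]
        if (net$edges$to[e] == v) u <- net$edges$from[e]
        if (is.null(u)) next
        if (abs(D[j, u] + net$edges$length[e] - D[j, v]) <= tol)
          s <- s + sigma[j, u]
      }
      sigma[j, v] <- s
    }
  }
  cb <- numeric(N)
  for (i in seq_len(N)) {
    tot <- 0
    for (j in seq_len(N)) for (k in seq_len(N)) {
      if (j == k || j == i || k == i) next
      if (abs(D[j, i] + D[i, k] - D[j, k]) <= tol && sigma[j, k] > 0)
        tot <- tot + sigma[j, i] * sigma[i, k] / sigma[j, k]
    }
    cb[i] <- tot / ((N - 1) * (N - 2))
  }
  cb
}

# single-row network_points helper
npt <- function(edge, offset) network_points(edge, offset)

# constructed K result for classification tests
fake_kfun <- function(t, obs, lower, mean_, upper) {
  structure(list(t = t, obs = obs, lower = lower, mean = mean_,
                 upper = upper, n = 10, rho = 1, n_sim = 99, alpha = 0.05,
                 mode = "auto"), class = "kfun_result")
}
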