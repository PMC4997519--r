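# Street centrality indices (multiple centrality assessment): betweenness,
# closeness and straightness per node, plus planar-KDE surfaces.

check_centrality_net <- function(net, min_nodes = 2L) {
  comp <- igraph::components(net$graph)
  if (comp$no > 1L)
    stop("centrality requires a connected network (", comp$no, " components)")
  if (nrow(net$nodes) < min_nodes)
    stop("network has fewer than ", min_nodes, " nodes")
}

#' Betweenness centrality
#'
#' Fraction of all-pairs shortest paths passing through each node,
#' \deqn{C^B_i = \frac{1}{(N-1)(N-2)} \sum_{j \ne k \ne i}
#'   \frac{n_{jk}(i)}{n_{jk}}}
#' over ordered pairs, where \eqn{n_{jk}} counts the equal-length shortest
#' paths from j to k (all ties counted, fractional credit) and
#' \eqn{n_{jk}(i)} those passing through i. Values lie in [0, 1]; the
#' centre of a path or star graph scores exactly 1.
#'
#' @param net a connected `road_network` with at least 3 nodes.
#' @return Numeric vector of per-node betweenness.
#' @export
betweenness_centrality <- function(net) {
  check_centrality_net(net, 3L)
  N <- nrow(net$nodes)
  b <- igraph::betweenness(net$graph, directed = FALSE,
                           weights = igraph::E(net$graph)$weight)
  # igraph sums over unordered pairs; the ordered-pair normalisation doubles it
  as.numeric(2 * b / ((N - 1) * (N - 2)))
}

#' Closeness centrality
#'
#' Inverse mean shortest-path distance,
#' \eqn{C^C_i = (N-1) / \sum_j d_{ij}}, in units of 1/metre: high where a
#' node is metrically close to all others.
#'
#' @param net a connected `road_network` with at least 2 nodes.
#' @return Numeric vector of per-node closeness (1/m).
#' @export
closeness_centrality <- function(net) {
  check_centrality_net(net, 2L)
  D <- node_dists(net)
  unname((nrow(net$nodes) - 1) / rowSums(D))
}

#' Straightness centrality
#'
#' Mean ratio of Euclidean to network distance,
#' \eqn{C^S_i = \frac{1}{N-1}\sum_j d^{Eu}_{ij} / d_{ij}}: 1 when the
#' network imposes no detour from node i, smaller the more circuitous the
#' routes. Coincident node pairs (both distances zero) are excluded with a
#' warning.
#'
#' @param net a connected `road_network` with at least 2 nodes.
#' @return Numeric vector of per-node straightness in (0, 1].
#' @export
straightness_centrality <- function(net) {
  check_centrality_net(net, 2L)
  N <- nrow(net$nodes)
  D <- node_dists(net)
  E <- as.matrix(stats::dist(cbind(net$nodes$x, net$nodes$y)))
  R <- E / D
  diag(R) <- 0
  degenerate <- E == 0 & D == 0
  diag(degenerate) <- FALSE
  denom <- rep(N - 1, N)
  if (any(degenerate)) {
    warning("coincident node pairs excluded from straightness")
    R[degenerate] <- 0
    denom <- denom - rowSums(degenerate)
  }
  unname(rowSums(R) / denom)
}

#' All three street centrality indices
#'
#' @param net a connected `road_network` with at least 3 nodes.
#' @return data.frame with columns `node`, `x`, `y`, `cb`, `cc`, `cs`.
#' @export
street_centrality <- function(net) {
  data.frame(node = net$nodes$id, x = net$nodes$x, y = net$nodes$y,
             cb = betweenness_centrality(net),
             cc = closeness_centrality(net),
             cs = straightness_centrality(net))
}

#' Planar KDE surface of a centrality index
#'
#' Smooths per-node centrality values into a continuous raster by planar
#' Gaussian KDE of the node locations weighted by their centrality, the
#' surface used for cell-wise correlation with facility density.
#'
#' @param net a `road_network`.
#' @param values finite per-node values (e.g. a column of
#'   [street_centrality()]).
#' @param bandwidth planar KDE bandwidth in metres (default 600).
#' @param grid a `raster_grid` template.
#' @return The filled `raster_grid`.
#' @export
centrality_surface <- function(net, values, bandwidth = 600, grid) {
  if (length(values) != nrow(net$nodes))
    stop("need one value per node")
  if (any(!is.finite(values))) stop("centrality values must be finite")
  planar_kde(cbind(net$nodes$x, net$nodes$y), values, bandwidth, grid)
}
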