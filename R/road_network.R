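# Road network data model: planar graph with metric edge geometry, on-network
# points located by (edge, offset), shortest-path distances and lixelization.

#' Construct a road network from line segments
#'
#' Builds the planar graph used by all analyses from a list of polyline
#' geometries. Endpoints closer than `snap_tol` are merged into a single
#' node, so slightly mismatched digitised junctions still connect.
#'
#' @param segments list of numeric matrices (two columns, x and y in metres),
#'   one polyline per road edge.
#' @param snap_tol node snap tolerance in metres; endpoints within this
#'   distance are treated as the same junction.
#' @param check_connected error if the resulting graph is not connected.
#' @return An object of class `road_network` with components `nodes`
#'   (data.frame: `id`, `x`, `y`), `edges` (data.frame: `id`, `from`, `to`,
#'   `length`), `geometry` (list of coordinate matrices) and
#'   `total_length`, the summed edge length \eqn{|S|}.
#' @export
road_network <- function(segments, snap_tol = 0.5, check_connected = TRUE) {
  if (!length(segments)) stop("no line segments supplied")
  segments <- lapply(segments, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    if (ncol(m) != 2L || nrow(m) < 2L)
      stop("each segment must be a matrix with >= 2 rows and 2 columns")
    m
  })

  # incremental endpoint dedup within snap tolerance
  node_xy <- matrix(numeric(0), ncol = 2L)
  find_node <- function(p) {
    if (nrow(node_xy) > 0L) {
      d2 <- (node_xy[, 1L] - p[1L])^2 + (node_xy[, 2L] - p[2L])^2
      j <- which.min(d2)
      if (d2[j] <= snap_tol^2) return(j)
    }
    node_xy <<- rbind(node_xy, p)
    nrow(node_xy)
  }

  nseg <- length(segments)
  from <- to <- integer(nseg)
  len <- numeric(nseg)
  for (i in seq_len(nseg)) {
    g <- segments[[i]]
    from[i] <- find_node(g[1L, ])
    to[i] <- find_node(g[nrow(g), ])
    len[i] <- polyline_length(g)
    if (len[i] <= 0) stop("edge ", i, " has non-positive length")
  }

  nodes <- data.frame(id = seq_len(nrow(node_xy)),
                      x = node_xy[, 1L], y = node_xy[, 2L])
  edges <- data.frame(id = seq_len(nseg), from = from, to = to, length = len)

  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  if (igraph::vcount(g) < nrow(nodes))
    g <- igraph::add_vertices(g, nrow(nodes) - igraph::vcount(g))
  igraph::E(g)$weight <- len

  if (check_connected) {
    comp <- igraph::components(g)
    if (comp$no > 1L)
      stop("network is not connected: ", comp$no, " connected components")
  }

  net <- list(nodes = nodes, edges = edges, geometry = segments,
              graph = g, total_length = sum(len), cache = new.env(parent = emptyenv()))
  class(net) <- "road_network"
  net
}

#' @export
print.road_network <- function(x, ...) {
  cat("road_network:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges, total length",
      format(x$total_length, digits = 8), "m\n")
  invisible(x)
}

polyline_length <- function(m) {
  d <- diff(m)
  sum(sqrt(rowSums(d^2)))
}

#' Total network length
#'
#' @param net a `road_network`.
#' @return Sum of edge lengths in metres.
#' @export
network_length <- function(net) net$total_length

#' Load a road network from file
#'
#' Reads a line layer from a GeoJSON FeatureCollection of LineString
#' features or a CSV edge list with a `wkt` column holding `LINESTRING`
#' geometries. Coordinates must be planar metres (a projected CRS);
#' longitude/latitude-looking coordinates are rejected.
#'
#' @inheritParams road_network
#' @param path path to the file.
#' @param format `"auto"` (by extension), `"geojson"` or `"csv"`.
#' @return A `road_network`.
#' @export
load_network <- function(path, format = c("auto", "geojson", "csv"),
                         snap_tol = 0.5) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "geojson"
  }
  segments <- if (format == "geojson") read_geojson_lines(path) else
    read_csv_lines(path)
  xs <- unlist(lapply(segments, function(m) m[, 1L]))
  ys <- unlist(lapply(segments, function(m) m[, 2L]))
  if (all(abs(xs) <= 180) && all(abs(ys) <= 90))
    stop("coordinates look geographic (degrees); a projected metric CRS is required")
  road_network(segments, snap_tol = snap_tol)
}

# cached node-to-node shortest path distance matrix (metres)
node_dists <- function(net) {
  if (is.null(net$cache$D)) {
    net$cache$D <- igraph::distances(net$graph, weights = igraph::E(net$graph)$weight)
  }
  net$cache$D
}

network_node_diameter <- function(net) max(node_dists(net))

#' On-network point set
#'
#' A set of points located on a `road_network` by edge id and offset in
#' metres from the edge's first node.
#'
#' @param edge integer vector of edge ids.
#' @param offset numeric vector of offsets (metres along the edge).
#' @return A data.frame of class `network_points`.
#' @export
network_points <- function(edge, offset) {
  stopifnot(length(edge) == length(offset))
  p <- data.frame(edge = as.integer(edge), offset = as.numeric(offset))
  class(p) <- c("network_points", "data.frame")
  p
}

validate_points <- function(net, pts) {
  if (!nrow(pts)) return(invisible(pts))
  if (any(pts$edge < 1L) || any(pts$edge > nrow(net$edges)))
    stop("point refers to an edge not on the network")
  len <- net$edges$length[pts$edge]
  if (any(pts$offset < -1e-9) || any(pts$offset > len + 1e-9))
    stop("point offset outside [0, edge length]")
  invisible(pts)
}

#' Snap planar points to the network
#'
#' Finds, for each input coordinate, the nearest point on any edge
#' (perpendicular foot or clamped endpoint). Ties are broken by the lowest
#' edge id, so snapping is deterministic.
#'
#' @param net a `road_network`.
#' @param xy numeric matrix (or vector of length 2) of planar coordinates.
#' @return list with `points` (a `network_points` set) and `dist`,
#'   the Euclidean snap distance of each input point.
#' @export
snap_points <- function(net, xy) {
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2L)
  xy <- as.matrix(xy)
  n <- nrow(xy)
  best_d2 <- rep(Inf, n)
  best_edge <- integer(n)
  best_off <- numeric(n)
  for (e in seq_along(net$geometry)) {
    g <- net$geometry[[e]]
    seg_len <- sqrt(rowSums(diff(g)^2))
    cum0 <- c(0, cumsum(seg_len))
    for (s in seq_len(nrow(g) - 1L)) {
      p0 <- g[s, ]; v <- g[s + 1L, ] - p0
      L2 <- sum(v^2)
      tpar <- ((xy[, 1L] - p0[1L]) * v[1L] + (xy[, 2L] - p0[2L]) * v[2L]) / L2
      tpar <- pmin(1, pmax(0, tpar))
      dx <- xy[, 1L] - (p0[1L] + tpar * v[1L])
      dy <- xy[, 2L] - (p0[2L] + tpar * v[2L])
      d2 <- dx^2 + dy^2
      upd <- d2 < best_d2 - 1e-12  # strict improvement: lowest edge id wins ties
      if (any(upd)) {
        best_d2[upd] <- d2[upd]
        best_edge[upd] <- e
        best_off[upd] <- cum0[s] + tpar[upd] * seg_len[s]
      }
    }
  }
  list(points = network_points(best_edge, best_off), dist = sqrt(best_d2))
}

#' Network shortest-path distance between on-network points
#'
#' Distances account for the partial offsets of both endpoints; a pair on
#' the same edge may still be connected more shortly around the rest of
#' the network, and that route is taken when shorter.
#'
#' @param net a `road_network`.
#' @param a,b `network_points` sets of sizes m and k.
#' @return An m x k matrix of distances in metres (dropped to a scalar when
#'   both sets have a single point).
#' @export
network_distance <- function(net, a, b) {
  d <- point_dist_matrix(net, a, b)
  if (length(d) == 1L) as.numeric(d) else d
}

# m x k cross-distance matrix; chunked over rows to bound memory
point_dist_matrix <- function(net, a, b, chunk = 4096L) {
  validate_points(net, a); validate_points(net, b)
  m <- nrow(a); k <- nrow(b)
  if (m == 0L || k == 0L) return(matrix(numeric(0), m, k))
  D <- node_dists(net)
  eb <- net$edges[b$edge, ]
  ob <- b$offset
  lb_rem <- eb$length - ob
  out <- matrix(0, m, k)
  for (i0 in seq(1L, m, by = chunk)) {
    idx <- i0:min(m, i0 + chunk - 1L)
    ea <- net$edges[a$edge[idx], ]
    oa <- a$offset[idx]
    la_rem <- ea$length - oa
    d1 <- D[ea$from, eb$from, drop = FALSE] + outer(oa, ob, "+")
    d2 <- D[ea$from, eb$to, drop = FALSE] + outer(oa, lb_rem, "+")
    d3 <- D[ea$to, eb$from, drop = FALSE] + outer(la_rem, ob, "+")
    d4 <- D[ea$to, eb$to, drop = FALSE] + outer(la_rem, lb_rem, "+")
    d <- pmin(d1, d2, d3, d4)
    same <- outer(a$edge[idx], b$edge, "==")
    if (any(same)) {
      direct <- abs(outer(oa, ob, "-"))
      d[same] <- pmin(d[same], direct[same])
    }
    out[idx, ] <- d
  }
  out
}

#' Subdivide the network into lixels
#'
#' Splits every edge into `ceiling(length / cell_size)` equal-length lixels
#' (linear pixels), the evaluation units of network density. Lixel lengths
#' never exceed `cell_size` and the lixels of an edge partition it exactly.
#'
#' @param net a `road_network`.
#' @param cell_size target lixel length in metres.
#' @return A data.frame of class `lixel_set` with columns `edge`, `start`,
#'   `end`, `centre` (offset of the midpoint) and `length`.
#' @export
subdivide_lixels <- function(net, cell_size) {
  if (cell_size <= 0) stop("cell_size must be > 0")
  per_edge <- lapply(seq_len(nrow(net$edges)), function(e) {
    len <- net$edges$length[e]
    nl <- ceiling(len / cell_size)
    w <- len / nl
    i <- seq_len(nl)
    data.frame(edge = e, start = (i - 1) * w, end = i * w, centre = (i - 0.5) * w,
               length = w)
  })
  lx <- do.call(rbind, per_edge)
  # force exact partition at the far end despite rounding
  lx$end[c(diff(lx$edge) != 0L, TRUE)] <- net$edges$length[lx$edge[c(diff(lx$edge) != 0L, TRUE)]]
  class(lx) <- c("lixel_set", "data.frame")
  lx
}

lixel_centres <- function(lx) network_points(lx$edge, lx$centre)

#' Planar coordinates of on-network points
#'
#' @param net a `road_network`.
#' @param pts a `network_points` set.
#' @return Matrix with columns x, y obtained by interpolating the edge
#'   polylines at each point's offset.
#' @export
point_coords <- function(net, pts) {
  validate_points(net, pts)
  out <- matrix(0, nrow(pts), 2L)
  for (i in seq_len(nrow(pts))) {
    g <- net$geometry[[pts$edge[i]]]
    out[i, ] <- interp_polyline(g, pts$offset[i])
  }
  colnames(out) <- c("x", "y")
  out
}

interp_polyline <- function(g, off) {
  seg_len <- sqrt(rowSums(diff(g)^2))
  cum <- c(0, cumsum(seg_len))
  off <- min(max(off, 0), cum[length(cum)])
  s <- findInterval(off, cum, rightmost.closed = TRUE)
  s <- min(s, length(seg_len))
  tpar <- if (seg_len[s] > 0) (off - cum[s]) / seg_len[s] else 0
  g[s, ] + tpar * (g[s + 1L, ] - g[s, ])
}
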