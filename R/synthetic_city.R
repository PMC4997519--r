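# Synthetic-city generator: grid road networks and network-constrained
# point processes (CSR, clustered, regular) with facility attributes
# (strength class, ownership, bed-count weights).

#' Rectangular grid road network
#'
#' Lattice of `rows` x `cols` nodes connected by horizontal and vertical
#' edges of length `spacing`. With `jitter > 0` the node positions are
#' perturbed uniformly by up to `jitter * spacing` in each coordinate
#' ("perturbed-grid" networks with unequal edge lengths).
#'
#' @param rows,cols lattice dimensions (>= 2).
#' @param spacing edge length in metres.
#' @param jitter fraction of `spacing` used as the perturbation half-width.
#' @param seed optional integer seed used when `jitter > 0`.
#' @return A `road_network`.
#' @export
make_grid_network <- function(rows, cols, spacing, jitter = 0, seed = NULL) {
  stopifnot(rows >= 2, cols >= 2, spacing > 0)
  xy <- cbind(rep((seq_len(cols) - 1) * spacing, times = rows),
              rep((seq_len(rows) - 1) * spacing, each = cols))
  if (jitter > 0) {
    if (!is.null(seed)) set.seed(seed)
    xy <- xy + matrix(stats::runif(length(xy), -jitter * spacing, jitter * spacing),
                      ncol = 2L)
  }
  node_at <- function(r, c) (r - 1L) * cols + c
  segs <- list()
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    if (c < cols) segs[[length(segs) + 1L]] <- xy[c(node_at(r, c), node_at(r, c + 1L)), ]
    if (r < rows) segs[[length(segs) + 1L]] <- xy[c(node_at(r, c), node_at(r + 1L, c)), ]
  }
  road_network(segs, snap_tol = min(0.5, spacing / 100))
}

#' Sample points under network CSR
#'
#' Complete spatial randomness on a network: an edge is chosen with
#' probability proportional to its length, then the offset is uniform on
#' the edge, so the point intensity is uniform per metre of network.
#'
#' @param net a `road_network`.
#' @param n number of points.
#' @param seed optional integer seed.
#' @return A `network_points` set of size `n`.
#' @export
sample_csr <- function(net, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n == 0L) return(network_points(integer(0), numeric(0)))
  len <- net$edges$length
  e <- sample.int(nrow(net$edges), n, replace = TRUE, prob = len)
  network_points(e, stats::runif(n) * len[e])
}

# random walk along the network: travel a given distance from a start
# point, choosing uniformly among incident edges at every junction
walk_along <- function(net, start, dist) {
  edge <- start$edge
  off <- start$offset
  len <- net$edges$length[edge]
  # initial direction: towards 'from' (-1) or 'to' (+1)
  dir <- if (stats::runif(1) < 0.5) -1 else 1
  remaining <- dist
  for (step in 1:200) {
    avail <- if (dir > 0) len - off else off
    if (remaining <= avail) {
      off <- off + dir * remaining
      return(network_points(edge, off))
    }
    remaining <- remaining - avail
    node <- if (dir > 0) net$edges$to[edge] else net$edges$from[edge]
    inc <- which(net$edges$from == node | net$edges$to == node)
    edge <- inc[sample.int(length(inc), 1L)]
    len <- net$edges$length[edge]
    if (net$edges$from[edge] == node) { off <- 0; dir <- 1 } else { off <- len; dir <- -1 }
  }
  network_points(edge, off)  # walk cap reached; return current location
}

#' Sample a clustered point process on the network
#'
#' Parents are drawn under network CSR; each child is displaced from its
#' parent by a network random walk whose length is half-normal with the
#' given scale (uniform branch choice at junctions). The process is
#' intrinsically network-constrained: children always lie on the network
#' at a controlled network distance from their parent.
#'
#' @param net a `road_network`.
#' @param n_parents number of cluster parents.
#' @param children_per_parent points per cluster.
#' @param scale half-normal scale of the displacement distance (metres).
#' @param seed optional integer seed.
#' @return A `network_points` set of `n_parents * children_per_parent`
#'   points.
#' @export
sample_clustered <- function(net, n_parents, children_per_parent, scale,
                             seed = NULL) {
  stopifnot(scale > 0)
  if (!is.null(seed)) set.seed(seed)
  parents <- sample_csr(net, n_parents)
  out <- vector("list", n_parents * children_per_parent)
  k <- 0L
  for (i in seq_len(n_parents)) {
    for (j in seq_len(children_per_parent)) {
      d <- abs(stats::rnorm(1, 0, scale))
      k <- k + 1L
      out[[k]] <- walk_along(net, parents[i, ], d)
    }
  }
  do.call(rbind_points, out)
}

#' Sample points clustered around fixed anchor events
#'
#' Each point picks an anchor uniformly at random and is displaced from it
#' by a half-normal network random walk, emulating facilities (for example
#' pharmacies) that locate near existing attractors (hospitals).
#'
#' @param net a `road_network`.
#' @param anchors a `network_points` set or `network_events` (locations
#'   are used) around which points concentrate.
#' @param n number of points.
#' @param scale half-normal displacement scale in metres.
#' @param seed optional integer seed.
#' @return A `network_points` set of size `n`.
#' @export
sample_cross_clustered <- function(net, anchors, n, scale, seed = NULL) {
  anchors <- as_network_points(anchors)
  if (!nrow(anchors)) stop("anchors must be non-empty")
  stopifnot(scale > 0)
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    i <- sample.int(nrow(anchors), 1L)
    d <- abs(stats::rnorm(1, 0, scale))
    out[[k]] <- walk_along(net, anchors[i, ], d)
  }
  do.call(rbind_points, out)
}

rbind_points <- function(...) {
  p <- do.call(rbind.data.frame, lapply(list(...), unclass))
  class(p) <- c("network_points", "data.frame")
  p
}

as_network_points <- function(x) {
  if (inherits(x, "network_events")) x$location else x
}

#' Deterministic regular (dispersed) point pattern
#'
#' Walks the edges in id order, proposing candidate positions every
#' `spacing / 10` metres, and keeps a candidate only if its network
#' distance to every already-kept point is at least `spacing`. The result
#' is deterministic and has minimum pairwise network distance >= `spacing`
#' whenever more than one point fits on the network.
#'
#' @param net a `road_network`.
#' @param spacing target minimum separation in metres.
#' @return A `network_points` set.
#' @export
sample_regular <- function(net, spacing) {
  stopifnot(spacing > 0)
  step <- spacing / 10
  cand <- do.call(rbind, lapply(seq_len(nrow(net$edges)), function(e) {
    len <- net$edges$length[e]
    offs <- seq(0, len, by = step)
    cbind(e, offs)
  }))
  kept <- network_points(cand[1L, 1L], cand[1L, 2L])
  for (i in 2:nrow(cand)) {
    p <- network_points(cand[i, 1L], cand[i, 2L])
    d <- point_dist_matrix(net, p, kept)
    if (all(d >= spacing)) kept <- rbind_points(kept, p)
  }
  kept
}

#' Reference facility counts by class and ownership
#'
#' The bundled tally of urban hospital counts used as default sampling
#' frequencies: five comprehensive-strength classes (first class strongest,
#' fifth class weakest) and two ownership groups, both summing to the same
#' facility total.
#'
#' @return list with data.frames `strength` (`class`, `count`) and
#'   `ownership` (`ownership`, `count`).
#' @export
hospital_class_counts <- function() {
  path <- system.file("extdata", "hospital_counts.csv", package = "netspat")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  list(strength = df[df$dimension == "strength", c("level", "count")],
       ownership = df[df$dimension == "ownership", c("level", "count")])
}

#' Configuration for facility attribute sampling
#'
#' Defaults reproduce the bundled count table: class proportions
#' 33/38/152/135/374 out of 732 and ownership 376 private : 356 public.
#' Bed-count ranges per class are package defaults chosen so that
#' first-class hospitals can exceed 1000 beds while fifth-class facilities
#' are near-zero-bed clinics; they are configurable, not empirical claims.
#'
#' @param class_probs probabilities of strength classes 1..5 (sum to 1).
#' @param ownership_probs named probabilities for `private` and `public`.
#' @param bed_ranges list of 5 numeric ranges `c(min, max)` of bed counts.
#' @param unit_weights if `TRUE` every facility gets weight 1 (the
#'   unweighted analysis mode).
#' @return list of class `attribute_config`.
#' @export
attribute_config <- function(class_probs = c(33, 38, 152, 135, 374) / 732,
                             ownership_probs = c(private = 376, public = 356) / 732,
                             bed_ranges = list(c(500, 2500), c(200, 800),
                                               c(50, 300), c(10, 100), c(0, 20)),
                             unit_weights = FALSE) {
  if (abs(sum(class_probs) - 1) > 1e-9)
    stop("class proportions must sum to 1")
  if (abs(sum(ownership_probs) - 1) > 1e-9)
    stop("ownership proportions must sum to 1")
  structure(list(class_probs = class_probs, ownership_probs = ownership_probs,
                 bed_ranges = bed_ranges, unit_weights = unit_weights),
            class = "attribute_config")
}

#' Facility events on the network
#'
#' @param location a `network_points` set.
#' @param weight non-negative numeric weights (bed counts).
#' @param strength_class integer class 1-5 or `NA`.
#' @param ownership `"public"`, `"private"` or `NA`.
#' @return list of class `network_events`.
#' @export
network_events <- function(location, weight = 1,
                           strength_class = NA_integer_, ownership = NA_character_) {
  n <- nrow(location)
  weight <- rep_len(as.numeric(weight), n)
  if (any(weight < 0)) stop("weights (bed counts) must be non-negative")
  strength_class <- rep_len(as.integer(strength_class), n)
  if (any(!is.na(strength_class) & !(strength_class %in% 1:5)))
    stop("strength_class must be in 1..5")
  ownership <- rep_len(as.character(ownership), n)
  if (any(!is.na(ownership) & !(ownership %in% c("public", "private"))))
    stop("ownership must be 'public' or 'private'")
  structure(list(location = location, weight = weight,
                 strength_class = strength_class, ownership = ownership),
            class = "network_events")
}

#' @export
print.network_events <- function(x, ...) {
  cat("network_events:", nrow(x$location), "events; total weight",
      format(sum(x$weight)), "\n")
  invisible(x)
}

n_events <- function(ev) nrow(ev$location)

subset_events <- function(ev, keep) {
  network_events(ev$location[keep, , drop = FALSE], ev$weight[keep],
                 ev$strength_class[keep], ev$ownership[keep])
}

#' Assign facility attributes to points
#'
#' Samples a strength class, an ownership group and a bed-count weight for
#' each point: classes and ownership from the configured proportions, bed
#' counts uniform in the class's configured range.
#'
#' @param points a `network_points` set.
#' @param config an [attribute_config()].
#' @param seed optional integer seed.
#' @return A `network_events` object.
#' @export
assign_attributes <- function(points, config = attribute_config(), seed = NULL) {
  if (!inherits(config, "attribute_config")) stop("config must be an attribute_config")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(points)
  cls <- sample.int(5L, n, replace = TRUE, prob = config$class_probs)
  own <- sample(names(config$ownership_probs), n, replace = TRUE,
                prob = config$ownership_probs)
  beds <- if (config$unit_weights) rep(1, n) else {
    vapply(cls, function(k) {
      rg <- config$bed_ranges[[k]]
      stats::runif(1, rg[1L], rg[2L])
    }, numeric(1))
  }
  network_events(points, weight = beds, strength_class = cls, ownership = own)
}

#' Simulate a complete synthetic city
#'
#' Convenience wrapper producing a grid road network, hospitals (clustered
#' along the network, with class/ownership/bed attributes) and pharmacies
#' concentrated around the hospitals. The default magnitudes mirror a
#' large-city study layout (732 hospitals, 569 pharmacies on a city-scale
#' grid); tests and the bundled demo use smaller values of the same shape.
#'
#' @param rows,cols,spacing grid network parameters.
#' @param n_hospitals,n_pharmacies facility counts.
#' @param hospital_scale,pharmacy_scale half-normal displacement scales in
#'   metres for hospital clustering and pharmacy-around-hospital clustering.
#' @param cluster_fraction fraction of hospitals placed in clusters; the
#'   rest are CSR background.
#' @param config an [attribute_config()].
#' @param seed integer seed.
#' @return list with `net`, `hospitals` (`network_events`) and
#'   `pharmacies` (`network_points`).
#' @export
simulate_city <- function(rows = 30, cols = 30, spacing = 200,
                          n_hospitals = 732, n_pharmacies = 569,
                          hospital_scale = 400, pharmacy_scale = 150,
                          cluster_fraction = 0.6,
                          config = attribute_config(), seed = 1) {
  set.seed(seed)
  net <- make_grid_network(rows, cols, spacing)
  n_clustered <- round(cluster_fraction * n_hospitals)
  n_parents <- max(1L, round(n_clustered / 15))
  cpp <- max(1L, round(n_clustered / n_parents))
  clust <- sample_clustered(net, n_parents, cpp, hospital_scale)
  n_bg <- max(0L, n_hospitals - nrow(clust))
  pts <- if (n_bg > 0) rbind_points(clust, sample_csr(net, n_bg)) else
    clust[seq_len(n_hospitals), , drop = FALSE]
  hospitals <- assign_attributes(pts, config)
  pharmacies <- sample_cross_clustered(net, hospitals, n_pharmacies,
                                       pharmacy_scale)
  list(net = net, hospitals = hospitals, pharmacies = pharmacies)
}
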