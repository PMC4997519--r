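# Network kernel density estimation: Gaussian kernel in shortest-path
# distance, optional per-event weight (bed count), evaluated at lixel
# centres; min-max normalization; rasterization; planar KDE.

#' Network kernel density estimation
#'
#' Estimates the density of point events over the network. At each lixel
#' centre s the density is
#' \deqn{\lambda(s) = \sum_i \frac{1}{r}\frac{1}{\sqrt{2\pi}}
#'   e^{-d(s,i)^2 / (2 r^2)}\, B_i}
#' where d is the shortest-path network distance, r the bandwidth and
#' B_i the event weight (bed count); contributions are truncated to zero
#' beyond the bandwidth (d > r). An event at distance zero contributes
#' fully, so an isolated facility produces a peak at its own location.
#' With `weighted = FALSE` all B_i are set to 1 (the plain, unweighted
#' estimator). No normalization by the number of events or total weight is
#' applied; the density is per metre of network, linear in the weights.
#'
#' @param net a `road_network`.
#' @param events a `network_events` object (or a `network_points` set,
#'   which gets unit weights).
#' @param lixels a `lixel_set`; defaults to [subdivide_lixels()] at
#'   `cell_size`.
#' @param bandwidth kernel bandwidth r in metres (default 600).
#' @param cell_size lixel length used when `lixels` is `NULL` (default 20).
#' @param weighted use the event weights (`TRUE`) or unit weights.
#' @return An object of class `density_field`: the lixel set, one
#'   `lambda` per lixel centre and the evaluation metadata.
#' @export
netkde <- function(net, events, lixels = NULL, bandwidth = 600,
                   cell_size = 20, weighted = TRUE) {
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  if (inherits(events, "network_points")) events <- network_events(events)
  validate_points(net, events$location)
  if (is.null(lixels)) lixels <- subdivide_lixels(net, cell_size)
  w <- if (weighted) events$weight else rep(1, n_events(events))
  centres <- lixel_centres(lixels)
  lambda <- numeric(nrow(lixels))
  if (n_events(events) > 0L) {
    chunk <- max(1L, floor(4e6 / max(1L, n_events(events))))
    for (i0 in seq(1L, nrow(lixels), by = chunk)) {
      idx <- i0:min(nrow(lixels), i0 + chunk - 1L)
      D <- point_dist_matrix(net, centres[idx, , drop = FALSE], events$location)
      K <- exp(-D^2 / (2 * bandwidth^2)) / (bandwidth * sqrt(2 * pi))
      K[D > bandwidth] <- 0
      lambda[idx] <- as.numeric(K %*% w)
    }
  }
  structure(list(lixels = lixels, lambda = lambda, bandwidth = bandwidth,
                 weighted = weighted, normalized = FALSE),
            class = "density_field")
}

#' @export
print.density_field <- function(x, ...) {
  cat("density_field:", nrow(x$lixels), "lixels; bandwidth", x$bandwidth,
      "m;", if (x$weighted) "weighted" else "unweighted",
      if (x$normalized) "(min-max normalized)" else "", "\n")
  cat("  lambda range:", format(range(x$lambda), digits = 6), "\n")
  invisible(x)
}

#' Min-max normalize a density field
#'
#' Rescales the densities to the unit interval,
#' \eqn{\lambda' = (\lambda - \min\lambda) / (\max\lambda - \min\lambda)},
#' so maps of different scenarios share a common 0-1 scale. A constant
#' field maps to all zeros.
#'
#' @param field a `density_field`.
#' @return The normalized `density_field`.
#' @export
normalize_field <- function(field) {
  if (!length(field$lambda)) stop("empty density field")
  rng <- range(field$lambda)
  field$lambda <- if (diff(rng) == 0) rep(0, length(field$lambda)) else
    (field$lambda - rng[1L]) / diff(rng)
  field$normalized <- TRUE
  field
}

#' Regular raster grid
#'
#' @param xmin,ymin coordinates of the lower-left corner.
#' @param cellsize cell edge length in metres.
#' @param nrow,ncol grid dimensions; values are stored with row 1 the
#'   southernmost row.
#' @param values optional matrix of cell values (`NA` = nodata).
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(xmin, ymin, cellsize, nrow, ncol, values = NULL) {
  stopifnot(cellsize > 0, nrow >= 1, ncol >= 1)
  if (is.null(values)) values <- matrix(NA_real_, nrow, ncol)
  stopifnot(base::nrow(values) == nrow, base::ncol(values) == ncol)
  structure(list(xmin = xmin, ymin = ymin, cellsize = cellsize,
                 nrow = nrow, ncol = ncol, values = values),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat("raster_grid:", x$nrow, "x", x$ncol, "cells of", x$cellsize, "m;",
      sum(!is.na(x$values)), "valid cells\n")
  invisible(x)
}

#' Grid specification covering a network
#'
#' @param net a `road_network`.
#' @param cellsize cell size in metres.
#' @param pad margin added around the network extent, in metres.
#' @return An empty `raster_grid` aligned to the padded network extent.
#' @export
grid_from_network <- function(net, cellsize = 20, pad = 0) {
  xs <- range(unlist(lapply(net$geometry, function(m) m[, 1L])))
  ys <- range(unlist(lapply(net$geometry, function(m) m[, 2L])))
  xmin <- xs[1L] - pad; ymin <- ys[1L] - pad
  nc <- max(1L, ceiling((xs[2L] + pad - xmin) / cellsize))
  nr <- max(1L, ceiling((ys[2L] + pad - ymin) / cellsize))
  raster_grid(xmin, ymin, cellsize, nr, nc)
}

cell_centres <- function(grid) {
  cx <- grid$xmin + (seq_len(grid$ncol) - 0.5) * grid$cellsize
  cy <- grid$ymin + (seq_len(grid$nrow) - 0.5) * grid$cellsize
  list(x = cx, y = cy)
}

same_geometry <- function(a, b) {
  isTRUE(all.equal(c(a$xmin, a$ymin, a$cellsize, a$nrow, a$ncol),
                   c(b$xmin, b$ymin, b$cellsize, b$nrow, b$ncol),
                   tolerance = 1e-9))
}

#' Rasterize a density field onto a grid
#'
#' Each cell takes the length-weighted mean density of the lixel portions
#' that geometrically intersect it; cells touched by no lixel are nodata.
#'
#' @param net the `road_network` the field was computed on.
#' @param field a `density_field`.
#' @param grid a `raster_grid` (geometry template; values are replaced).
#' @return The filled `raster_grid`.
#' @export
rasterize_field <- function(net, field, grid) {
  acc_len <- matrix(0, grid$nrow, grid$ncol)
  acc_val <- matrix(0, grid$nrow, grid$ncol)
  lx <- field$lixels
  for (i in seq_len(nrow(lx))) {
    parts <- polyline_portion(net$geometry[[lx$edge[i]]], lx$start[i], lx$end[i])
    for (p in parts) {
      pieces <- clip_segment_grid(p$p0, p$p1, grid)
      if (!nrow(pieces)) next
      for (j in seq_len(nrow(pieces))) {
        r <- pieces[j, 1L]; c <- pieces[j, 2L]; L <- pieces[j, 3L]
        acc_len[r, c] <- acc_len[r, c] + L
        acc_val[r, c] <- acc_val[r, c] + L * field$lambda[i]
      }
    }
  }
  vals <- acc_val / acc_len
  vals[acc_len == 0] <- NA_real_
  grid$values <- vals
  grid
}

# straight sub-segments of a polyline between two arc-length offsets
polyline_portion <- function(g, start, end) {
  seg_len <- sqrt(rowSums(diff(g)^2))
  cum <- c(0, cumsum(seg_len))
  total <- cum[length(cum)]
  start <- max(0, min(start, total)); end <- max(start, min(end, total))
  parts <- list()
  for (s in seq_along(seg_len)) {
    a <- max(start, cum[s]); b <- min(end, cum[s + 1L])
    if (b - a <= 1e-12) next
    t0 <- (a - cum[s]) / seg_len[s]; t1 <- (b - cum[s]) / seg_len[s]
    v <- g[s + 1L, ] - g[s, ]
    parts[[length(parts) + 1L]] <-
      list(p0 = g[s, ] + t0 * v, p1 = g[s, ] + t1 * v)
  }
  parts
}

# split a straight segment at grid lines; returns matrix (row, col, length)
clip_segment_grid <- function(p0, p1, grid) {
  v <- p1 - p0
  L <- sqrt(sum(v^2))
  if (L <= 0) return(matrix(numeric(0), 0, 3L))
  ts <- c(0, 1)
  for (axis in 1:2) {
    orig <- if (axis == 1) grid$xmin else grid$ymin
    if (abs(v[axis]) > 1e-12) {
      js <- seq(ceiling((min(p0[axis], p1[axis]) - orig) / grid$cellsize),
                floor((max(p0[axis], p1[axis]) - orig) / grid$cellsize))
      tt <- (orig + js * grid$cellsize - p0[axis]) / v[axis]
      ts <- c(ts, tt[tt > 0 & tt < 1])
    }
  }
  ts <- sort(unique(ts))
  out <- matrix(0, 0, 3L)
  for (j in seq_len(length(ts) - 1L)) {
    tm <- (ts[j] + ts[j + 1L]) / 2
    pm <- p0 + tm * v
    c_ <- floor((pm[1L] - grid$xmin) / grid$cellsize) + 1L
    r_ <- floor((pm[2L] - grid$ymin) / grid$cellsize) + 1L
    if (r_ < 1L || r_ > grid$nrow || c_ < 1L || c_ > grid$ncol) next
    out <- rbind(out, c(r_, c_, (ts[j + 1L] - ts[j]) * L))
  }
  out
}

#' Planar kernel density estimation on a grid
#'
#' Ordinary 2-D Gaussian KDE evaluated at the cell centres, with the same
#' truncation convention as the network estimator: a point contributes
#' \eqn{w\, e^{-d^2/(2h^2)} / (2\pi h^2)} when its Euclidean distance d to
#' the cell centre is at most the bandwidth h, and nothing beyond. Used
#' for centrality surfaces and for smoothing facility fields onto the
#' common raster framework.
#'
#' @param xy matrix of point coordinates.
#' @param weights per-point weights (recycled).
#' @param bandwidth Gaussian bandwidth h in metres.
#' @param grid a `raster_grid` template.
#' @return The filled `raster_grid` (all cells valid).
#' @export
planar_kde <- function(xy, weights = 1, bandwidth, grid) {
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2L)
  xy <- as.matrix(xy)
  w <- rep_len(as.numeric(weights), nrow(xy))
  cc <- cell_centres(grid)
  vals <- matrix(0, grid$nrow, grid$ncol)
  norm <- 1 / (2 * pi * bandwidth^2)
  for (i in seq_len(nrow(xy))) {
    dx2 <- (cc$x - xy[i, 1L])^2
    dy2 <- (cc$y - xy[i, 2L])^2
    D2 <- outer(dy2, dx2, "+")
    Kc <- norm * exp(-D2 / (2 * bandwidth^2))
    Kc[D2 > bandwidth^2] <- 0
    vals <- vals + w[i] * Kc
  }
  grid$values <- vals
  grid
}
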