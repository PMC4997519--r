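# End-to-end workflow: load layers, optional scope mask, weighted and
# unweighted NetKDE, auto/cross K-functions, centrality surfaces,
# rasterization and the category x centrality correlation table.

#' Pipeline run configuration
#'
#' @param network,hospitals,pharmacies input layers: file paths, in-memory
#'   objects (`road_network`, `network_events`, `network_points`) or
#'   `NULL` (pharmacies optional).
#' @param mask optional polygon (two-column vertex matrix or path to a CSV
#'   with columns x, y) restricting the study scope.
#' @param bandwidth NetKDE and planar-KDE bandwidth in metres.
#' @param cell_size lixel and raster cell size in metres.
#' @param t_grid K-function distances (`NULL` = default grid).
#' @param n_sim,alpha Monte Carlo envelope settings.
#' @param seed integer seed driving every stochastic stage.
#' @param out_dir output directory (created if missing).
#' @return list of class `run_config`.
#' @export
run_config <- function(network, hospitals, pharmacies = NULL, mask = NULL,
                       bandwidth = 600, cell_size = 20, t_grid = NULL,
                       n_sim = 99, alpha = 0.05, seed = 1,
                       out_dir = tempfile("netspat_run")) {
  stopifnot(bandwidth > 0, cell_size > 0)
  structure(list(network = network, hospitals = hospitals,
                 pharmacies = pharmacies, mask = mask,
                 bandwidth = bandwidth, cell_size = cell_size,
                 t_grid = t_grid, n_sim = n_sim, alpha = alpha,
                 seed = seed, out_dir = out_dir),
            class = "run_config")
}

#' Read a pipeline configuration file
#'
#' Flat `key = value` text; `#` starts a comment. Recognised keys are the
#' arguments of [run_config()]; numeric values are converted.
#'
#' @param path path to the config file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- stats::setNames(lapply(kv, function(p) p[2L]),
                          vapply(kv, `[[`, character(1), 1L))
  num <- function(k, d) if (!is.null(vals[[k]])) as.numeric(vals[[k]]) else d
  chr <- function(k, d = NULL) if (!is.null(vals[[k]])) vals[[k]] else d
  if (is.null(vals$network) || is.null(vals$hospitals))
    stop("config must name 'network' and 'hospitals' inputs")
  run_config(network = chr("network"), hospitals = chr("hospitals"),
             pharmacies = chr("pharmacies"), mask = chr("mask"),
             bandwidth = num("bandwidth", 600), cell_size = num("cell_size", 20),
             n_sim = num("n_sim", 99), alpha = num("alpha", 0.05),
             seed = num("seed", 1),
             out_dir = chr("out_dir", tempfile("netspat_run")))
}

# ---- scope mask ------------------------------------------------------------

point_in_polygon <- function(xy, poly) {
  # even-odd ray casting
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(xy))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    cross <- ((yi > xy[, 2L]) != (yj > xy[, 2L])) &
      (xy[, 1L] < (xj - xi) * (xy[, 2L] - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross & !is.na(cross))
    j <- i
  }
  inside
}

clip_polyline_polygon <- function(g, poly) {
  pieces <- list()
  for (s in seq_len(nrow(g) - 1L)) {
    p0 <- g[s, ]; p1 <- g[s + 1L, ]
    v <- p1 - p0
    ts <- c(0, 1)
    nq <- nrow(poly)
    j <- nq
    for (i in seq_len(nq)) {
      q0 <- poly[j, ]; q1 <- poly[i, ]; j <- i
      w <- q1 - q0
      den <- v[1L] * w[2L] - v[2L] * w[1L]
      if (abs(den) < 1e-12) next
      tt <- ((q0[1L] - p0[1L]) * w[2L] - (q0[2L] - p0[2L]) * w[1L]) / den
      uu <- ((q0[1L] - p0[1L]) * v[2L] - (q0[2L] - p0[2L]) * v[1L]) / den
      if (tt > 0 && tt < 1 && uu >= 0 && uu <= 1) ts <- c(ts, tt)
    }
    ts <- sort(unique(ts))
    for (k in seq_len(length(ts) - 1L)) {
      tm <- (ts[k] + ts[k + 1L]) / 2
      mid <- matrix(p0 + tm * v, ncol = 2L)
      if (point_in_polygon(mid, poly)) {
        pieces[[length(pieces) + 1L]] <- rbind(p0 + ts[k] * v, p0 + ts[k + 1L] * v)
      }
    }
  }
  pieces
}

#' Restrict network and points to a study scope
#'
#' Clips every edge to the polygon (portions crossing the boundary are cut
#' at the intersection, interior portions kept), rebuilds the subnetwork
#' with a recomputed total length, and keeps the points falling inside.
#' If clipping disconnects the network the largest connected component is
#' retained with a warning, since all downstream distances require
#' connectivity.
#'
#' @param net a `road_network`.
#' @param points a `network_points` set or `network_events`.
#' @param polygon two-column matrix of polygon vertices (closed implicitly).
#' @return list with `net` (the clipped subnetwork), `points` (surviving
#'   points snapped onto it) and `keep` (logical index into the input
#'   points).
#' @export
scope_mask <- function(net, points, polygon) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3L) stop("polygon needs at least 3 vertices")
  segs <- list()
  for (e in seq_along(net$geometry))
    segs <- c(segs, clip_polyline_polygon(net$geometry[[e]], polygon))
  if (!length(segs)) stop("scope mask leaves no network")
  sub <- road_network(segs, snap_tol = 1e-6, check_connected = FALSE)
  comp <- igraph::components(sub$graph)
  if (comp$no > 1L) {
    warning("masked network has ", comp$no,
            " components; keeping the largest")
    big <- which.max(comp$csize)
    keep_edge <- comp$membership[sub$edges$from] == big
    sub <- road_network(sub$geometry[keep_edge], snap_tol = 1e-6)
  }
  loc <- as_network_points(points)
  xy <- point_coords(net, loc)
  keep <- point_in_polygon(xy, polygon)
  if (!any(keep)) stop("scope mask leaves no points")
  snapped <- snap_points(sub, xy[keep, , drop = FALSE])$points
  out_pts <- if (inherits(points, "network_events")) {
    ev <- subset_events(points, keep)
    ev$location <- snapped
    ev
  } else snapped
  list(net = sub, points = out_pts, keep = keep)
}

# ---- category fields -------------------------------------------------------

#' Facility-category density rasters on a common grid
#'
#' For each of the eight conventional categories (five strength classes,
#' two ownership groups, all facilities) computes the weighted NetKDE of
#' the subset and smooths it onto the planar grid: the lixel centres,
#' weighted by density times lixel length, are spread with a planar
#' Gaussian kernel of the same bandwidth. Categories with no facilities
#' yield an all-zero raster.
#'
#' @param net a `road_network`.
#' @param events a `network_events` object with class/ownership attributes.
#' @param grid a `raster_grid` template.
#' @param bandwidth kernel bandwidth in metres.
#' @param lixels optional precomputed `lixel_set`.
#' @param cell_size lixel size when `lixels` is `NULL`.
#' @return Named list of 8 `raster_grid`s.
#' @export
facility_category_fields <- function(net, events, grid, bandwidth = 600,
                                     lixels = NULL, cell_size = 20) {
  if (is.null(lixels)) lixels <- subdivide_lixels(net, cell_size)
  class_names <- c("First class", "Second class", "Third class",
                   "Fourth class", "Fifth class")
  subsets <- c(
    stats::setNames(lapply(1:5, function(k)
      !is.na(events$strength_class) & events$strength_class == k), class_names),
    list(Public = !is.na(events$ownership) & events$ownership == "public",
         Private = !is.na(events$ownership) & events$ownership == "private",
         `All hospitals` = rep(TRUE, n_events(events))))
  cxy <- point_coords(net, lixel_centres(lixels))
  lapply(subsets, function(keep) {
    if (!any(keep)) {
      g <- grid; g$values <- matrix(0, grid$nrow, grid$ncol)
      return(g)
    }
    f <- netkde(net, subset_events(events, keep), lixels = lixels,
                bandwidth = bandwidth, weighted = TRUE)
    planar_kde(cxy, f$lambda * lixels$length, bandwidth, grid)
  })
}

# ---- full run --------------------------------------------------------------

resolve_network <- function(x) {
  if (inherits(x, "road_network")) x else load_network(x)
}

resolve_events <- function(net, x) {
  if (inherits(x, "network_events")) return(x)
  if (inherits(x, "network_points")) return(network_events(x))
  df <- read_points(x)
  sp <- snap_points(net, cbind(df$x, df$y))
  w <- ifelse(is.na(df$beds), 1, df$beds)
  own <- ifelse(df$ownership %in% c("public", "private"), df$ownership,
                NA_character_)
  network_events(sp$points, weight = w, strength_class = df$class,
                 ownership = own)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input loading, optional scope masking, weighted and
#' unweighted NetKDE of all facilities (normalized and rasterized), auto
#' K-functions of all facilities, of the combined first/second-class
#' subset and of the remaining facilities, the cross K-function from
#' facilities to pharmacies (skipped with a warning when no pharmacy layer
#' is given), street centrality with planar surfaces, the eight
#' facility-category rasters, and the category x centrality Spearman
#' table. All stochastic stages derive from the single configured seed, so
#' a rerun with the same configuration is reproducible. Outputs are
#' written under `config$out_dir` as CSV / GeoJSON / ESRI ASCII / JSON.
#'
#' @param config a [run_config()].
#' @return list of class `run_report`: per-stage status, the parameters
#'   used, an output file manifest and summary statistics.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character(0)
  stages <- list()
  emit <- function(name, writer) {
    path <- file.path(config$out_dir, name)
    writer(path)
    manifest <<- c(manifest, path)
    path
  }
  stage <- function(name, expr) {
    res <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    stages[[name]] <<- "ok"
    res
  }

  set.seed(config$seed)
  net <- stage("load_network", resolve_network(config$network))
  hospitals <- stage("load_hospitals", resolve_events(net, config$hospitals))
  pharmacies <- if (!is.null(config$pharmacies)) {
    p <- config$pharmacies
    if (inherits(p, "network_points") || inherits(p, "network_events"))
      as_network_points(p)
    else snap_points(net, as.matrix(read_points(p)[, c("x", "y")]))$points
  } else NULL

  if (!is.null(config$mask)) {
    poly <- if (is.character(config$mask))
      as.matrix(utils::read.csv(config$mask)[, c("x", "y")]) else
        as.matrix(config$mask)
    m <- stage("scope_mask", scope_mask(net, hospitals, poly))
    net <- m$net
    hospitals <- m$points
    if (!is.null(pharmacies)) {
      keep <- point_in_polygon(point_coords(resolve_network(config$network),
                                            pharmacies), poly)
      pharmacies <- snap_points(net, point_coords(resolve_network(config$network),
                                                  pharmacies)[keep, , drop = FALSE])$points
    }
  }

  lixels <- subdivide_lixels(net, config$cell_size)
  grid <- grid_from_network(net, config$cell_size)

  # density stage: weighted vs unweighted contrast
  kde_w <- stage("netkde_weighted",
                 normalize_field(netkde(net, hospitals, lixels = lixels,
                                        bandwidth = config$bandwidth)))
  kde_u <- stage("netkde_unweighted",
                 normalize_field(netkde(net, hospitals, lixels = lixels,
                                        bandwidth = config$bandwidth,
                                        weighted = FALSE)))
  emit("netkde_weighted.csv", function(p) write_field_csv(kde_w, p))
  emit("netkde_unweighted.csv", function(p) write_field_csv(kde_u, p))
  emit("netkde_weighted.asc", function(p)
    write_esri_ascii(rasterize_field(net, kde_w, grid), p))
  emit("netkde_unweighted.asc", function(p)
    write_esri_ascii(rasterize_field(net, kde_u, grid), p))

  # K-function scenarios
  kfuns <- list()
  kfuns$all <- stage("auto_k_all",
                     network_kfun(net, hospitals, t_grid = config$t_grid,
                                  n_sim = config$n_sim, alpha = config$alpha,
                                  seed = config$seed))
  top <- !is.na(hospitals$strength_class) & hospitals$strength_class <= 2L
  if (sum(top) >= 2L)
    kfuns$first_second <- stage("auto_k_first_second",
                                network_kfun(net, subset_events(hospitals, top),
                                             t_grid = config$t_grid,
                                             n_sim = config$n_sim,
                                             alpha = config$alpha,
                                             seed = config$seed + 1L))
  if (sum(!top) >= 2L)
    kfuns$other <- stage("auto_k_other",
                         network_kfun(net, subset_events(hospitals, !top),
                                      t_grid = config$t_grid,
                                      n_sim = config$n_sim,
                                      alpha = config$alpha,
                                      seed = config$seed + 2L))
  if (!is.null(pharmacies)) {
    kfuns$cross <- stage("cross_k_pharmacies",
                         network_cross_kfun(net, hospitals, pharmacies,
                                            t_grid = config$t_grid,
                                            n_sim = config$n_sim,
                                            alpha = config$alpha,
                                            seed = config$seed + 3L))
  } else {
    warning("no pharmacy layer supplied; cross K-function skipped")
    stages$cross_k_pharmacies <- "skipped"
  }
  for (nm in names(kfuns))
    emit(paste0("kfun_", nm, ".csv"),
         local({f <- kfuns[[nm]]; function(p) write_kfun_csv(f, p)}))

  # centrality + surfaces
  cent <- stage("centrality", street_centrality(net))
  emit("centrality.csv", function(p) utils::write.csv(cent, p, row.names = FALSE))
  surfaces <- stage("centrality_surfaces", list(
    CS = centrality_surface(net, cent$cs, config$bandwidth, grid),
    CC = centrality_surface(net, cent$cc, config$bandwidth, grid),
    CB = centrality_surface(net, cent$cb, config$bandwidth, grid)))
  for (nm in names(surfaces))
    emit(paste0("centrality_", nm, ".asc"),
         local({s <- surfaces[[nm]]; function(p) write_esri_ascii(s, p)}))

  # category fields + correlation
  fields <- stage("category_fields",
                  facility_category_fields(net, hospitals, grid,
                                           bandwidth = config$bandwidth,
                                           lixels = lixels))
  for (nm in names(fields))
    emit(paste0("field_", gsub(" ", "_", tolower(nm)), ".asc"),
         local({f <- fields[[nm]]; function(p) write_esri_ascii(f, p)}))
  ctab <- stage("correlation", correlation_table(fields, surfaces))
  emit("correlation_table.csv", function(p)
    utils::write.csv(as.data.frame(ctab), p, row.names = FALSE))

  classifications <- lapply(kfuns, function(k) classify_pattern(k)$summary)
  top_idx <- order(kde_w$lambda, decreasing = TRUE)[seq_len(min(5L, length(kde_w$lambda)))]
  report <- list(
    stages = stages,
    parameters = list(bandwidth = config$bandwidth,
                      cell_size = config$cell_size, n_sim = config$n_sim,
                      alpha = config$alpha, seed = config$seed,
                      network_length = net$total_length,
                      n_hospitals = n_events(hospitals),
                      n_pharmacies = if (is.null(pharmacies)) 0L else nrow(pharmacies)),
    manifest = manifest,
    summary = list(
      pattern = classifications,
      top_density_lixels = data.frame(
        edge = kde_w$lixels$edge[top_idx],
        centre = kde_w$lixels$centre[top_idx],
        lambda = kde_w$lambda[top_idx]),
      correlation = as.data.frame(ctab)))
  class(report) <- "run_report"
  report_path <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(list(stages = stages, parameters = report$parameters,
                            manifest = manifest,
                            pattern = classifications),
                       report_path, auto_unbox = TRUE, digits = NA)
  report$manifest <- c(manifest, report_path)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("netspat run:", length(x$manifest), "output files\n")
  cat("  stages:", paste(names(x$stages), unlist(x$stages), sep = "=",
                         collapse = ", "), "\n")
  cat("  patterns:", paste(names(x$summary$pattern),
                           unlist(x$summary$pattern), sep = "=",
                           collapse = ", "), "\n")
  invisible(x)
}
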