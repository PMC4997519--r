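# Readers and writers for the plain-text interchange formats the package
# uses: GeoJSON (via jsonlite), CSV layers and ESRI ASCII rasters.

read_geojson_lines <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  segs <- list()
  for (f in feats) {
    geom <- if (identical(f$type, "Feature")) f$geometry else f
    if (identical(geom$type, "LineString")) {
      segs[[length(segs) + 1L]] <- coords_to_matrix(geom$coordinates)
    } else if (identical(geom$type, "MultiLineString")) {
      for (part in geom$coordinates)
        segs[[length(segs) + 1L]] <- coords_to_matrix(part)
    } else {
      stop("unsupported geometry type in line layer: ", geom$type)
    }
  }
  segs
}

coords_to_matrix <- function(cc) {
  m <- do.call(rbind, lapply(cc, function(p) c(p[[1L]], p[[2L]])))
  storage.mode(m) <- "double"
  m
}

read_csv_lines <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"wkt" %in% names(df)) stop("CSV line layer needs a 'wkt' column")
  lapply(df$wkt, parse_wkt_linestring)
}

parse_wkt_linestring <- function(s) {
  body <- sub("^\\s*LINESTRING\\s*\\(", "", s, ignore.case = TRUE)
  body <- sub("\\)\\s*$", "", body)
  pts <- strsplit(body, ",")[[1L]]
  m <- do.call(rbind, lapply(pts, function(p)
    as.numeric(strsplit(trimws(p), "\\s+")[[1L]][1:2])))
  m
}

#' Read a facility point layer
#'
#' Accepts GeoJSON Point features (attributes in `properties`) or a CSV
#' with columns `x`, `y` and optionally `beds`, `class`, `ownership`.
#'
#' @param path path to the file.
#' @return data.frame with columns `x`, `y`, `beds`, `class`, `ownership`
#'   (missing attributes filled with `NA` / weight 1).
#' @export
read_points <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("x", "y") %in% names(df))) stop("point CSV needs x and y columns")
  } else {
    gj <- jsonlite::read_json(path, simplifyVector = FALSE)
    feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
    df <- do.call(rbind, lapply(feats, function(f) {
      p <- f$geometry$coordinates
      pr <- f$properties
      data.frame(x = p[[1L]], y = p[[2L]],
                 beds = if (!is.null(pr$beds)) pr$beds else NA_real_,
                 class = if (!is.null(pr$class)) pr$class else NA_integer_,
                 ownership = if (!is.null(pr$ownership)) pr$ownership else NA_character_,
                 stringsAsFactors = FALSE)
    }))
  }
  if (is.null(df$beds)) df$beds <- NA_real_
  if (is.null(df$class)) df$class <- NA_integer_
  if (is.null(df$ownership)) df$ownership <- NA_character_
  df
}

#' Write points as GeoJSON
#'
#' @param xy matrix of planar coordinates.
#' @param path output path.
#' @param properties optional data.frame of per-point attributes.
#' @export
write_geojson_points <- function(xy, path, properties = NULL) {
  feats <- lapply(seq_len(nrow(xy)), function(i) {
    pr <- if (is.null(properties)) setNames(list(), character(0)) else
      as.list(properties[i, , drop = FALSE])
    list(type = "Feature",
         geometry = list(type = "Point", coordinates = c(xy[i, 1L], xy[i, 2L])),
         properties = pr)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a line layer as GeoJSON
#'
#' @param segments list of coordinate matrices (or a `road_network`, whose
#'   edge geometries are written with their ids).
#' @param path output path.
#' @param properties optional data.frame of per-line attributes.
#' @export
write_geojson_lines <- function(segments, path, properties = NULL) {
  if (inherits(segments, "road_network")) segments <- segments$geometry
  feats <- lapply(seq_along(segments), function(i) {
    m <- segments[[i]]
    pr <- if (is.null(properties)) setNames(list(), character(0)) else
      as.list(properties[i, , drop = FALSE])
    list(type = "Feature",
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(m)), function(r) m[r, ])),
         properties = pr)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a raster grid as an ESRI ASCII grid
#'
#' @param grid a `raster_grid`.
#' @param path output path (conventionally `.asc`).
#' @param nodata value written for missing cells.
#' @export
write_esri_ascii <- function(grid, path, nodata = -9999) {
  v <- grid$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", grid$ncol),
    paste("nrows", grid$nrow),
    paste("xllcorner", format(grid$xmin, digits = 12)),
    paste("yllcorner", format(grid$ymin, digits = 12)),
    paste("cellsize", format(grid$cellsize, digits = 12)),
    paste("NODATA_value", nodata)), con)
  # ESRI ASCII rows run north to south; internal rows run south to north
  for (r in rev(seq_len(grid$nrow)))
    writeLines(paste(format(v[r, ], digits = 10), collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path path to the `.asc` file.
#' @return A `raster_grid`.
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  vals <- lapply(lines[i:length(lines)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1L]]))
  m <- do.call(rbind, vals)
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  nod <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  m[m == nod] <- NA_real_
  raster_grid(hdr$xllcorner, hdr$yllcorner, hdr$cellsize,
              nrow = hdr$nrows, ncol = hdr$ncols, values = m)
}

#' Export a density field as CSV
#'
#' One row per lixel: `edge`, `start`, `end`, `lambda`.
#'
#' @param field a `density_field`.
#' @param path output path.
#' @export
write_field_csv <- function(field, path) {
  df <- data.frame(edge = field$lixels$edge, start = field$lixels$start,
                   end = field$lixels$end, lambda = field$lambda)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a K-function result as CSV
#'
#' Columns `t`, `obs`, `lower`, `mean`, `upper` and the per-distance
#' `label` from the envelope classification.
#'
#' @param result a `kfun_result`.
#' @param path output path.
#' @export
write_kfun_csv <- function(result, path) {
  cl <- classify_pattern(result)
  df <- data.frame(t = result$t, obs = result$obs, lower = result$lower,
                   mean = result$mean, upper = result$upper, label = cl$labels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
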