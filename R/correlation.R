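# Raster-level Spearman correlation between facility density and street
# centrality surfaces.

#' Spearman correlation between two co-registered rasters
#'
#' Ranks the cell values of each layer (average ranks on ties) over the
#' cells valid in both layers and returns the Pearson correlation of the
#' ranks, with a p-value from the t approximation on n - 2 degrees of
#' freedom.
#'
#' @param a,b `raster_grid`s with identical geometry.
#' @param include_empty treat nodata cells present in both layers as zeros
#'   instead of dropping them.
#' @return list with `r`, `p`, `n` (cells used) and `constant` (`TRUE`
#'   when either layer is constant over the mask, leaving r undefined).
#' @export
raster_spearman <- function(a, b, include_empty = FALSE) {
  if (!same_geometry(a, b)) stop("raster grids are not co-registered")
  va <- as.numeric(a$values)
  vb <- as.numeric(b$values)
  if (include_empty) {
    va[is.na(va)] <- 0
    vb[is.na(vb)] <- 0
  }
  ok <- !is.na(va) & !is.na(vb)
  n <- sum(ok)
  if (n < 3L) stop("need at least 3 jointly valid cells")
  va <- va[ok]; vb <- vb[ok]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n, constant = TRUE))
  }
  r <- stats::cor(rank(va), rank(vb))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(r = r, p = p, n = n, constant = FALSE)
}

#' Facility-category versus centrality correlation table
#'
#' Spearman correlation of every facility-category density raster against
#' every centrality surface, computed over the shared valid-cell mask (the
#' intersection of all layers' valid cells, so each correlation uses the
#' same n).
#'
#' @param facility_fields named list of `raster_grid`s, one per facility
#'   category. The conventional eight categories are `First class` ...
#'   `Fifth class`, `Public`, `Private`, `All hospitals`.
#' @param centrality_surfaces named list of `raster_grid`s, conventionally
#'   `CS`, `CC`, `CB`.
#' @param include_empty see [raster_spearman()].
#' @return data.frame of class `correlation_table` with columns
#'   `category`, `index`, `r`, `p`, `n`.
#' @export
correlation_table <- function(facility_fields, centrality_surfaces,
                              include_empty = FALSE) {
  if (is.null(names(facility_fields)) || is.null(names(centrality_surfaces)))
    stop("both layer lists must be named")
  layers <- c(facility_fields, centrality_surfaces)
  ref <- layers[[1L]]
  for (nm in names(layers)) {
    if (!inherits(layers[[nm]], "raster_grid"))
      stop("missing or invalid raster layer: ", nm)
    if (!same_geometry(layers[[nm]], ref))
      stop("layer not co-registered with the others: ", nm)
  }
  # shared mask: cells valid in every layer
  mask <- Reduce(`&`, lapply(layers, function(g) !is.na(g$values)))
  if (include_empty) mask[] <- TRUE
  masked <- function(g) {
    v <- g$values
    if (include_empty) v[is.na(v)] <- 0
    v[!mask] <- NA_real_
    raster_grid(g$xmin, g$ymin, g$cellsize, g$nrow, g$ncol, v)
  }
  rows <- expand.grid(category = names(facility_fields),
                      index = names(centrality_surfaces),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(rows)), function(i) {
    raster_spearman(masked(facility_fields[[rows$category[i]]]),
                    masked(centrality_surfaces[[rows$index[i]]]))
  })
  out <- data.frame(category = rows$category, index = rows$index,
                    r = vapply(res, `[[`, numeric(1), "r"),
                    p = vapply(res, `[[`, numeric(1), "p"),
                    n = vapply(res, `[[`, numeric(1), "n"))
  class(out) <- c("correlation_table", "data.frame")
  out
}

#' @export
print.correlation_table <- function(x, digits = 3, ...) {
  wide <- stats::reshape(as.data.frame(x)[, c("category", "index", "r")],
                         idvar = "category", timevar = "index",
                         direction = "wide")
  names(wide) <- sub("^r\\.", "", names(wide))
  wide[-1L] <- lapply(wide[-1L], round, digits)
  print(wide, row.names = FALSE)
  invisible(x)
}
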