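#' Georeferenced raster container
#'
#' A minimal single-CRS raster: a numeric array `values` of dim
#' `(nrow, ncol, nbands)`, an affine geotransform with origin at the top-left
#' corner, square axis-aligned pixels, and half-open pixel cells
#' `[x_lo, x_hi) x (y_lo, y_hi]` so that every point belongs to exactly one
#' pixel. Row 1 is the northernmost row.
#'
#' @param values numeric array `(nrow, ncol, nbands)` or a matrix (one band).
#' @param xmin x coordinate of the left edge (meters).
#' @param ymax y coordinate of the top edge (meters).
#' @param res pixel size in meters (one number, square pixels).
#' @param crs CRS identifier string.
#' @param band_names optional character vector of band names.
#' @return an object of class `sdm_raster`.
#' @export
new_raster <- function(values, xmin, ymax, res, crs = "local", band_names = NULL) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  stopifnot(length(dim(values)) == 3, res > 0)
  if (is.null(band_names)) band_names <- paste0("band_", seq_len(dim(values)[3]))
  structure(
    list(values = values, xmin = xmin, ymax = ymax, res = res,
         crs = crs, band_names = band_names),
    class = "sdm_raster")
}

#' @export
print.sdm_raster <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<sdm_raster> %d x %d pixels, %d band(s), %g m/px\n", d[1], d[2], d[3], x$res))
  e <- raster_extent(x)
  cat(sprintf("  extent: x [%g, %g], y [%g, %g], crs: %s\n",
              e["xmin"], e["xmax"], e["ymin"], e["ymax"], x$crs))
  invisible(x)
}

#' Raster extent
#' @param r an `sdm_raster`.
#' @return named vector `xmin, xmax, ymin, ymax`.
#' @export
raster_extent <- function(r) {
  d <- dim(r$values)
  c(xmin = r$xmin, xmax = r$xmin + d[2] * r$res,
    ymin = r$ymax - d[1] * r$res, ymax = r$ymax)
}

# Pixel (row, col) containing (x, y) under the half-open cell convention;
# NA when outside the grid.
xy_to_cell <- function(r, x, y) {
  d <- dim(r$values)
  col <- floor((x - r$xmin) / r$res) + 1
  row <- floor((r$ymax - y) / r$res) + 1
  # top edge belongs to row 1 (y == ymax), interior edges to the cell below
  row[y == r$ymax] <- 1
  bad <- row < 1 | row > d[1] | col < 1 | col > d[2]
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

# Center coordinates of pixel (row, col).
cell_to_xy <- function(r, row, col) {
  cbind(x = r$xmin + (col - 0.5) * r$res,
        y = r$ymax - (row - 0.5) * r$res)
}

#' Band values at a point
#'
#' @param r an `sdm_raster`.
#' @param x,y point coordinates (meters, raster CRS).
#' @return numeric vector of band values, or `NULL` when the point falls
#'   outside the grid or on a nodata (`NA`) pixel.
#' @export
raster_value_at <- function(r, x, y) {
  rc <- xy_to_cell(r, x, y)
  if (is.na(rc[1, "row"])) return(NULL)
  v <- r$values[rc[1, "row"], rc[1, "col"], ]
  if (anyNA(v)) return(NULL)
  v
}

points_in_raster <- function(r, x, y) {
  rc <- xy_to_cell(r, x, y)
  ok <- !is.na(rc[, "row"])
  if (any(ok)) {
    idx <- which(ok)
    nb <- dim(r$values)[3]
    for (i in idx) {
      if (anyNA(r$values[rc[i, "row"], rc[i, "col"], ])) ok[i] <- FALSE
    }
  }
  ok
}

#' Read and write rasters
#'
#' Rasters are stored as multi-page 32-bit TIFF (one page per band) plus a
#' JSON sidecar `<path>.json` holding the geotransform, CRS, band names, and
#' per-band scale/offset used to map values into the unit interval for
#' storage.
#'
#' @param r an `sdm_raster`.
#' @param path file path ending in `.tif`.
#' @return `read_raster()` returns an `sdm_raster`.
#' @export
write_raster <- function(r, path) {
  d <- dim(r$values)
  lo <- apply(r$values, 3, min, na.rm = TRUE)
  hi <- apply(r$values, 3, max, na.rm = TRUE)
  span <- ifelse(hi > lo, hi - lo, 1)
  pages <- lapply(seq_len(d[3]), function(b) {
    m <- (r$values[, , b] - lo[b]) / span[b]
    m[is.na(m)] <- 0
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(xmin = r$xmin, ymax = r$ymax, res = r$res, crs = r$crs,
               band_names = r$band_names, scale = as.numeric(span),
               offset = as.numeric(lo))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path, call. = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  vals <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (b in seq_along(pages)) {
    pg <- pages[[b]]
    if (!is.matrix(pg)) pg <- pg[, , 1]
    vals[, , b] <- pg * meta$scale[b] + meta$offset[b]
  }
  new_raster(vals, meta$xmin, meta$ymax, meta$res, meta$crs, meta$band_names)
}

# Point-in-polygon by ray casting; points lying on an edge or vertex count as
# inside (closed polygon convention). poly: two-column matrix, implicitly closed.
point_in_polygon <- function(x, y, poly) {
  px <- poly[, 1]; py <- poly[, 2]
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1))
  out <- logical(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]; yi <- y[i]
    inside <- FALSE
    on_edge <- FALSE
    for (s in seq_len(n)) {
      x1 <- px[j[s]]; y1 <- py[j[s]]; x2 <- px[s]; y2 <- py[s]
      # on-segment test
      cr <- (x2 - x1) * (yi - y1) - (y2 - y1) * (xi - x1)
      if (abs(cr) < 1e-9 &&
          xi >= min(x1, x2) - 1e-9 && xi <= max(x1, x2) + 1e-9 &&
          yi >= min(y1, y2) - 1e-9 && yi <= max(y1, y2) + 1e-9) {
        on_edge <- TRUE
        break
      }
      if ((y1 > yi) != (y2 > yi)) {
        xint <- x1 + (yi - y1) * (x2 - x1) / (y2 - y1)
        if (xi < xint) inside <- !inside
      }
    }
    out[i] <- inside || on_edge
  }
  out
}
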