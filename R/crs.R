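#' Coordinate reference helpers
#'
#' All geometry in the package lives in a single projected CRS with meter
#' units, because every filtering radius (deduplication, neighbor imputation,
#' leakage exclusion) is metric. Longitude/latitude inputs are reprojected on
#' read through a spherical transverse Mercator centered on the data, which is
#' exactly invertible and metrically faithful at the regional scales the
#' models operate on.
#'
#' A local CRS is encoded as the string `"LTM:lon0=<deg>,lat0=<deg>"`.
#'
#' @param lon0,lat0 center of projection in decimal degrees.
#' @return `local_crs()` returns the CRS string.
#' @export
local_crs <- function(lon0, lat0) {
  sprintf("LTM:lon0=%.10g,lat0=%.10g", lon0, lat0)
}

is_lonlat_crs <- function(crs) {
  !is.null(crs) && toupper(crs) %in% c("EPSG:4326", "WGS84", "LONLAT", "OGC:CRS84")
}

parse_local_crs <- function(crs) {
  if (!is.character(crs) || !startsWith(crs, "LTM:")) {
    stop("unknown CRS identifier: ", crs, call. = FALSE)
  }
  body <- sub("^LTM:", "", crs)
  parts <- strsplit(body, ",", fixed = TRUE)[[1]]
  kv <- vapply(strsplit(parts, "=", fixed = TRUE), function(p) as.numeric(p[2]), 0)
  names(kv) <- vapply(strsplit(parts, "=", fixed = TRUE), `[`, "", 1)
  if (anyNA(kv[c("lon0", "lat0")])) stop("malformed local CRS: ", crs, call. = FALSE)
  list(lon0 = kv[["lon0"]], lat0 = kv[["lat0"]])
}

.EARTH_R <- 6378137           # sphere radius, meters
.M_PER_DEG_LAT <- pi * .EARTH_R / 180

#' Project longitude/latitude to local metric coordinates
#'
#' Spherical transverse Mercator about the CRS center; `lonlat_from_xy()` is
#' its exact inverse.
#'
#' @param lon,lat coordinates in decimal degrees.
#' @param crs a local CRS string from [local_crs()].
#' @return two-column matrix of x, y in meters.
#' @export
xy_from_lonlat <- function(lon, lat, crs) {
  p <- parse_local_crs(crs)
  lam <- (lon - p$lon0) * pi / 180
  phi <- lat * pi / 180
  phi0 <- p$lat0 * pi / 180
  b <- cos(phi) * sin(lam)
  x <- .EARTH_R / 2 * log((1 + b) / (1 - b))
  y <- .EARTH_R * (atan2(tan(phi), cos(lam)) - phi0)
  cbind(x = x, y = y)
}

#' @rdname xy_from_lonlat
#' @param x,y projected coordinates in meters.
#' @return two-column matrix of lon, lat in decimal degrees.
#' @export
lonlat_from_xy <- function(x, y, crs) {
  p <- parse_local_crs(crs)
  phi0 <- p$lat0 * pi / 180
  d <- y / .EARTH_R + phi0
  phi <- asin(sin(d) / cosh(x / .EARTH_R))
  lam <- atan2(sinh(x / .EARTH_R), cos(d))
  cbind(lon = p$lon0 + lam * 180 / pi, lat = phi * 180 / pi)
}

# Latitude for projected anchors; used by the latitudinal block splitter.
latitude_of <- function(x, y, crs = NULL) {
  if (!is.null(crs) && is.character(crs) && startsWith(crs, "LTM:")) {
    lonlat_from_xy(x, y, crs)[, "lat"]
  } else {
    y / .M_PER_DEG_LAT
  }
}
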