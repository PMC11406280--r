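#' Read a raw occurrence table
#'
#' Reads a CSV of georeferenced single-species records and returns a validated
#' occurrence data frame in a projected, meter-unit CRS. Required columns are
#' `record_id`, `species`, and either `x`/`y` (already projected) or
#' `lon`/`lat` together with a lon/lat `crs` (e.g. `"EPSG:4326"`), in which
#' case coordinates are reprojected through a transverse Mercator centered on
#' the data and the resulting local CRS is attached as the `crs` attribute.
#'
#' Rows with an empty species name or non-finite coordinates are dropped and
#' counted in a message. When a `coord_uncertainty_m` column is present,
#' records with uncertainty above `max_uncertainty_m` are dropped as well;
#' when it is absent that filter is skipped with a warning.
#'
#' @param path CSV file path.
#' @param crs CRS identifier of the input coordinates. Use `"EPSG:4326"` for
#'   lon/lat input; any other value asserts the coordinates are already in
#'   projected meters.
#' @param max_uncertainty_m maximum admissible coordinate uncertainty radius,
#'   meters.
#' @return a `data.frame` with columns `record_id`, `species`, `x`, `y` and
#'   any further columns present in the file, with attribute `crs`.
#' @export
read_occurrences <- function(path, crs = "local", max_uncertainty_m = 120) {
  if (!file.exists(path)) stop("occurrence file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lonlat <- is_lonlat_crs(crs)
  need <- c("record_id", "species", if (lonlat) c("lon", "lat") else c("x", "y"))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("occurrence table lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out_crs <- crs
  if (lonlat) {
    out_crs <- local_crs(mean(df$lon, na.rm = TRUE), mean(df$lat, na.rm = TRUE))
    xy <- xy_from_lonlat(df$lon, df$lat, out_crs)
    df$x <- xy[, "x"]; df$y <- xy[, "y"]
  }
  n0 <- nrow(df)
  keep <- !is.na(df$species) & nzchar(trimws(df$species)) &
    is.finite(df$x) & is.finite(df$y)
  if ("coord_uncertainty_m" %in% names(df)) {
    keep <- keep & (is.na(df$coord_uncertainty_m) |
                      df$coord_uncertainty_m <= max_uncertainty_m)
  } else {
    warning("no coord_uncertainty_m column; uncertainty filter skipped", call. = FALSE)
  }
  df <- df[keep, , drop = FALSE]
  if (anyDuplicated(df$record_id)) {
    stop("record_id values are not unique", call. = FALSE)
  }
  dropped <- n0 - nrow(df)
  if (dropped > 0) {
    message(sprintf("read_occurrences: dropped %d of %d rows (missing species, non-finite coordinates, or uncertainty > %g m)",
                    dropped, n0, max_uncertainty_m))
  }
  rownames(df) <- NULL
  attr(df, "crs") <- out_crs
  df
}

#' Deduplicate same-species records within a radius
#'
#' Greedy single pass in stable input order, independently per species: a
#' record is kept iff no previously kept record of the same species lies
#' within `radius_m` (Euclidean distance, projected meters). The first record
#' wins ties; output order is input order.
#'
#' @param occs occurrence data frame (see [read_occurrences()]).
#' @param radius_m deduplication radius, meters.
#' @return the thinned occurrence data frame.
#' @export
dedup_within_radius <- function(occs, radius_m = 150) {
  stopifnot(radius_m > 0)
  keep <- logical(nrow(occs))
  r2 <- radius_m^2
  for (idx in split(seq_len(nrow(occs)), occs$species)) {
    kx <- numeric(0); ky <- numeric(0)
    for (i in idx) {
      if (length(kx) == 0 ||
          min((kx - occs$x[i])^2 + (ky - occs$y[i])^2) > r2) {
        keep[i] <- TRUE
        kx <- c(kx, occs$x[i]); ky <- c(ky, occs$y[i])
      }
    }
  }
  out <- occs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "crs") <- attr(occs, "crs")
  out
}

#' Remove spatially confined species
#'
#' Removes every record of a species whose occurrences all lie within
#' `radius_m` of the species' coordinate centroid. Such species occupy (at the
#' data's resolution) a single image footprint and carry no range signal; a
#' single-record species is trivially confined.
#'
#' @inheritParams dedup_within_radius
#' @param radius_m confinement radius, meters.
#' @return occurrence data frame without confined species.
#' @export
drop_confined_species <- function(occs, radius_m = 256) {
  stopifnot(radius_m > 0)
  confined <- vapply(split(seq_len(nrow(occs)), occs$species), function(idx) {
    cx <- mean(occs$x[idx]); cy <- mean(occs$y[idx])
    max(sqrt((occs$x[idx] - cx)^2 + (occs$y[idx] - cy)^2)) <= radius_m
  }, TRUE)
  bad <- names(confined)[confined]
  out <- occs[!(occs$species %in% bad), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "crs") <- attr(occs, "crs")
  out
}

#' Clip occurrences to a boundary polygon and raster extents
#'
#' Keeps records lying inside the boundary polygon (closed: points on the
#' edge are kept) and inside the valid-data extent of every provided raster
#' (the containing pixel must exist and hold no `NA` band value).
#'
#' @inheritParams dedup_within_radius
#' @param boundary two-column matrix of polygon vertices (working CRS), or
#'   `NULL` to skip the polygon test.
#' @param rasters list of [sdm_raster][new_raster] objects, possibly empty.
#' @return clipped occurrence data frame; warns when the result is empty.
#' @export
clip_to_extent <- function(occs, boundary = NULL, rasters = list()) {
  keep <- rep(TRUE, nrow(occs))
  if (!is.null(boundary)) {
    keep <- keep & point_in_polygon(occs$x, occs$y, boundary)
  }
  for (r in rasters) {
    keep <- keep & points_in_raster(r, occs$x, occs$y)
  }
  out <- occs[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("clip_to_extent: no occurrences remain", call. = FALSE)
  rownames(out) <- NULL
  attr(out, "crs") <- attr(occs, "crs")
  out
}

#' Remove rare species from label sets
#'
#' Runs after neighbor imputation, so a species' count is its total number of
#' label-set memberships (anchors whose community list contains it). Species
#' below `min_count` are removed from every label set; anchors left with an
#' empty species set are dropped.
#'
#' @param labels an `sdm_labels` object (see [neighbor_impute()]).
#' @param min_count minimum number of label-set memberships.
#' @return filtered `sdm_labels`.
#' @export
filter_min_count <- function(labels, min_count = 500) {
  counts <- table(unlist(labels$species, use.names = FALSE))
  keep_sp <- names(counts)[counts >= min_count]
  if (length(keep_sp) == 0) {
    stop("filter_min_count: every species falls below min_count = ", min_count,
         call. = FALSE)
  }
  new_sets <- lapply(labels$species, function(s) s[s %in% keep_sp])
  nonempty <- lengths(new_sets) > 0
  structure(
    list(anchors = labels$anchors[nonempty, , drop = FALSE],
         species = new_sets[nonempty],
         radius_m = labels$radius_m,
         crs = labels$crs),
    class = "sdm_labels")
}
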