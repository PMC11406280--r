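#' Strided sliding-window prediction map
#'
#' Tiles the imagery raster with `window_px` x `window_px` windows at the
#' given stride, predicts the per-species presence probabilities of every
#' window, and assigns them to that window's output cell — so a stride of 50
#' on 1 m imagery yields a 50 m-resolution species probability stack. The
#' climate vector is sampled at each window's center. Output cells are
#' georeferenced to their window centers.
#'
#' @param model a trained `sdm_model`.
#' @param imagery 4-band imagery [sdm_raster][new_raster].
#' @param climate climate raster (required by climate-using architectures).
#' @param normalizer `sdm_normalizer` for the climate raster.
#' @param window_px prediction window side, pixels.
#' @param stride_px stride between window origins, pixels.
#' @param batch_size windows predicted per forward pass.
#' @return an `sdm_prediction_map`: list with `probs` (`S x R x C` array),
#'   `xmin`, `ymax`, `res` (meters between output cell centers), `crs`,
#'   `species`, `window_px`, `stride_px`.
#' @export
predict_map <- function(model, imagery, climate = NULL, normalizer = NULL,
                        window_px = 256, stride_px = 50, batch_size = 64) {
  stopifnot(stride_px >= 1)
  d <- dim(imagery$values)
  if (d[1] < window_px || d[2] < window_px) {
    stop("imagery raster smaller than the prediction window", call. = FALSE)
  }
  R <- (d[1] - window_px) %/% stride_px + 1
  C <- (d[2] - window_px) %/% stride_px + 1
  s_ <- model$config$S
  use_clim <- model$arch %in% c("climate_mlp", "fused")
  use_img <- model$arch %in% c("image_encoder", "fused")
  probs <- array(NA_real_, c(s_, R, C))
  cells <- expand.grid(r = seq_len(R), c = seq_len(C))
  for (start in seq(1, nrow(cells), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, nrow(cells))
    nb <- length(idx)
    imgs <- if (use_img) array(0, c(d[3], window_px, window_px, nb)) else NULL
    clims <- if (use_clim) matrix(0, length(normalizer$mean), nb) else NULL
    keep <- rep(TRUE, nb)
    for (j in seq_len(nb)) {
      r <- cells$r[idx[j]]; cc <- cells$c[idx[j]]
      r0 <- (r - 1) * stride_px
      c0 <- (cc - 1) * stride_px
      ctr_x <- imagery$xmin + (c0 + window_px / 2) * imagery$res
      ctr_y <- imagery$ymax - (r0 + window_px / 2) * imagery$res
      if (use_img) {
        imgs[, , , j] <- aperm(imagery$values[(r0 + 1):(r0 + window_px),
                                              (c0 + 1):(c0 + window_px), ,
                                              drop = FALSE], c(3, 1, 2))
      }
      if (use_clim) {
        v <- extract_climate_vector(climate, normalizer, ctr_x, ctr_y)
        if (is.null(v)) keep[j] <- FALSE else clims[, j] <- v
      }
    }
    if (!any(keep)) next
    p <- predict_probabilities(model, list(
      images = if (use_img) imgs[, , , keep, drop = FALSE] else NULL,
      climate = if (use_clim) clims[, keep, drop = FALSE] else NULL))
    krows <- which(keep)
    for (j in seq_along(krows)) {
      probs[, cells$r[idx[krows[j]]], cells$c[idx[krows[j]]]] <- p[j, ]
    }
  }
  structure(
    list(probs = probs,
         xmin = imagery$xmin + (window_px / 2) * imagery$res,
         ymax = imagery$ymax - (window_px / 2) * imagery$res,
         res = stride_px * imagery$res,
         crs = imagery$crs,
         species = model$index$species,
         window_px = window_px, stride_px = stride_px),
    class = "sdm_prediction_map")
}

#' @export
print.sdm_prediction_map <- function(x, ...) {
  d <- dim(x$probs)
  cat(sprintf("<sdm_prediction_map> %d species x %d x %d cells | %g m between centers (window %d px, stride %d px)\n",
              d[1], d[2], d[3], x$res, x$window_px, x$stride_px))
  invisible(x)
}

# Stack the probabilities of two grid offsets and return the per-cell
# Euclidean norm of their difference.
offset_norm <- function(P, dr, dc) {
  d <- dim(P)
  r1 <- max(1, 1 - dr):min(d[2], d[2] - dr)
  c1 <- max(1, 1 - dc):min(d[3], d[3] - dc)
  A <- P[, r1, c1, drop = FALSE]
  B <- P[, r1 + dr, c1 + dc, drop = FALSE]
  nrm <- sqrt(apply((A - B)^2, c(2, 3), sum))
  list(rows = r1, cols = c1, norm = nrm)
}

#' Spatial community change (ecotone edge detection)
#'
#' For each map cell, the Euclidean norms of the differences between its
#' species-probability vector and those of its (up to) eight neighbors are
#' averaged — an edge-detection filter over community composition. High
#' values flag community turnover: ecotones, habitat fragmentation edges,
#' land-use boundaries. Border cells average over their existing neighbors.
#'
#' @param map an `sdm_prediction_map` (or bare `S x R x C` array).
#' @return `R x C` matrix of averaged one-neighbor Euclidean norms.
#' @export
spatial_community_change <- function(map) {
  P <- if (inherits(map, "sdm_prediction_map")) map$probs else map
  d <- dim(P)
  if (d[2] < 2 && d[3] < 2) {
    warning("single-cell map: spatial change is identically zero", call. = FALSE)
    return(matrix(0, d[2], d[3]))
  }
  acc <- matrix(0, d[2], d[3])
  cnt <- matrix(0, d[2], d[3])
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    if (d[2] - abs(dr) < 1 || d[3] - abs(dc) < 1) next
    o <- offset_norm(P, dr, dc)
    acc[o$rows, o$cols] <- acc[o$rows, o$cols] + o$norm
    cnt[o$rows, o$cols] <- cnt[o$rows, o$cols] + 1
  }
  acc / pmax(cnt, 1)
}

#' Temporal community change
#'
#' Per-cell Euclidean distance between the species-probability vectors of two
#' co-registered prediction maps (two dates of the same scene): the aggregate
#' magnitude of per-species change between the timepoints.
#'
#' @param map_a,map_b `sdm_prediction_map`s (or `S x R x C` arrays) on
#'   identical grids and species indices.
#' @return `R x C` matrix of per-cell Euclidean distances.
#' @export
temporal_community_change <- function(map_a, map_b) {
  A <- if (inherits(map_a, "sdm_prediction_map")) map_a$probs else map_a
  B <- if (inherits(map_b, "sdm_prediction_map")) map_b$probs else map_b
  if (!all(dim(A) == dim(B))) stop("prediction maps have mismatched grids", call. = FALSE)
  if (inherits(map_a, "sdm_prediction_map") && inherits(map_b, "sdm_prediction_map") &&
      !identical(map_a$species, map_b$species)) {
    stop("prediction maps have mismatched species indices", call. = FALSE)
  }
  sqrt(apply((A - B)^2, c(2, 3), sum))
}

# z-score every band over the raster, then block-average to cells of
# cell_m meters; returns (bands, R, C).
standardize_and_block <- function(raster, cell_m) {
  d <- dim(raster$values)
  px_per_cell <- max(1L, as.integer(round(cell_m / raster$res)))
  R <- d[1] %/% px_per_cell
  C <- d[2] %/% px_per_cell
  if (R < 1 || C < 1) stop("raster smaller than one aggregation cell", call. = FALSE)
  out <- array(0, c(d[3], R, C))
  for (b in seq_len(d[3])) {
    v <- raster$values[, , b]
    s <- stats::sd(as.numeric(v))
    v <- if (s > 0) (v - mean(v)) / s else v * 0
    v <- v[seq_len(R * px_per_cell), seq_len(C * px_per_cell)]
    # average px_per_cell x px_per_cell blocks
    v <- array(v, c(px_per_cell, R, px_per_cell * C))
    v <- colMeans(v)                       # (R, px_per_cell * C)
    v <- array(v, c(R, px_per_cell, C))
    out[b, , ] <- apply(v, c(1, 3), mean)
  }
  out
}

#' Community-change baselines on raw imagery
#'
#' The null comparison for the community-change statistics: per-band z-scored
#' raw pixel values are block-averaged to `cell_m`-meter cells, and the same
#' spatial (8-neighbor averaged norm over band vectors) or temporal (per-cell
#' Euclidean distance) operator is applied to the band vectors instead of
#' species probabilities.
#'
#' @param raster_a imagery raster.
#' @param raster_b second-date raster (temporal mode only).
#' @param mode `"spatial"` or `"temporal"`.
#' @param cell_m aggregation cell size, meters.
#' @return `R x C` matrix of change values.
#' @export
raw_image_change <- function(raster_a, raster_b = NULL,
                             mode = c("spatial", "temporal"), cell_m = 256) {
  mode <- match.arg(mode)
  A <- standardize_and_block(raster_a, cell_m)
  if (mode == "spatial") return(spatial_community_change(A))
  stopifnot(!is.null(raster_b))
  if (!all(dim(raster_a$values) == dim(raster_b$values)) ||
      raster_a$xmin != raster_b$xmin || raster_a$ymax != raster_b$ymax) {
    stop("rasters are not co-registered", call. = FALSE)
  }
  B <- standardize_and_block(raster_b, cell_m)
  temporal_community_change(A, B)
}

#' Write a prediction map to disk
#'
#' One TIFF page per species plus a JSON sidecar carrying the species index,
#' geotransform, window and stride.
#'
#' @param map an `sdm_prediction_map`.
#' @param path output path ending in `.tif`.
#' @export
write_prediction_map <- function(map, path) {
  d <- dim(map$probs)
  r <- new_raster(aperm(map$probs, c(2, 3, 1)), map$xmin, map$ymax, map$res,
                  map$crs, band_names = map$species)
  write_raster(r, path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  meta$window_px <- map$window_px
  meta$stride_px <- map$stride_px
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
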