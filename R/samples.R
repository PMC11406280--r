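#' Extract a centered image patch
#'
#' Returns the `size_px` x `size_px` window of a 4-band imagery raster whose
#' center pixel contains `(x, y)`. Values are returned as reflectance in
#' `[0, 1]` in a `(bands, size_px, size_px)` array. Anchors whose window would
#' exceed the raster are dropped (returns `NULL`) rather than padded — padding
#' would fabricate land cover.
#'
#' @param raster imagery [sdm_raster][new_raster] (values already in `[0,1]`).
#' @param x,y anchor coordinates, meters.
#' @param size_px window side length in pixels.
#' @return `(nbands, size_px, size_px)` array, or `NULL` (drop signal).
#' @export
extract_image_patch <- function(raster, x, y, size_px = 256) {
  d <- dim(raster$values)
  rc <- xy_to_cell(raster, x, y)
  if (is.na(rc[1, "row"])) return(NULL)
  r0 <- rc[1, "row"] - floor(size_px / 2)
  c0 <- rc[1, "col"] - floor(size_px / 2)
  if (r0 < 1 || c0 < 1 || r0 + size_px - 1 > d[1] || c0 + size_px - 1 > d[2]) {
    return(NULL)
  }
  patch <- raster$values[r0:(r0 + size_px - 1), c0:(c0 + size_px - 1), , drop = FALSE]
  aperm(patch, c(3, 1, 2))
}

#' Fit a per-band climate normalizer
#'
#' Computes per-band mean and population standard deviation over all valid
#' pixels of the climate raster (optionally restricted to pixels whose centers
#' fall inside `mask`). A constant band is a fatal error: it cannot be
#' standardized.
#'
#' @param raster climate [sdm_raster][new_raster] with B bands.
#' @param mask optional two-column polygon matrix restricting the fit region.
#' @return an `sdm_normalizer`: list with `mean` and `sd` vectors (length B).
#' @export
fit_climate_normalizer <- function(raster, mask = NULL) {
  d <- dim(raster$values)
  sel <- matrix(TRUE, d[1], d[2])
  if (!is.null(mask)) {
    ctr_col <- raster$xmin + (seq_len(d[2]) - 0.5) * raster$res
    ctr_row <- raster$ymax - (seq_len(d[1]) - 0.5) * raster$res
    xs <- rep(ctr_col, each = d[1])
    ys <- rep(ctr_row, times = d[2])
    sel <- matrix(point_in_polygon(xs, ys, mask), d[1], d[2])
  }
  mu <- numeric(d[3]); sd_ <- numeric(d[3])
  for (b in seq_len(d[3])) {
    v <- raster$values[, , b][sel]
    v <- v[!is.na(v)]
    if (length(v) == 0) stop("climate band ", b, " has no valid pixels", call. = FALSE)
    mu[b] <- mean(v)
    sd_[b] <- sqrt(mean((v - mu[b])^2))
    if (sd_[b] == 0) {
      stop("climate band ", b, " is constant within the mask (SD = 0)", call. = FALSE)
    }
  }
  structure(list(mean = mu, sd = sd_, band_names = raster$band_names),
            class = "sdm_normalizer")
}

#' Standardized climate vector at a point
#'
#' Value of the pixel containing `(x, y)` (no interpolation), standardized per
#' band by the fitted normalizer.
#'
#' @param raster climate raster.
#' @param normalizer an `sdm_normalizer` from [fit_climate_normalizer()].
#' @param x,y point coordinates, meters.
#' @return length-B numeric vector, or `NULL` when the point is outside the
#'   raster or on a nodata pixel (drop signal).
#' @export
extract_climate_vector <- function(raster, normalizer, x, y) {
  v <- raster_value_at(raster, x, y)
  if (is.null(v)) return(NULL)
  (v - normalizer$mean) / normalizer$sd
}

#' Serialize a climate normalizer
#' @param normalizer an `sdm_normalizer`.
#' @param path JSON path; `read_normalizer()` reads it back.
#' @export
write_normalizer <- function(normalizer, path) {
  jsonlite::write_json(unclass(normalizer), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_normalizer
#' @export
read_normalizer <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean = j$mean, sd = j$sd, band_names = j$band_names),
            class = "sdm_normalizer")
}

#' Assemble training samples
#'
#' Inner join of label sets, image patches, climate vectors and completeness
#' weights on anchor id. Anchors missing any component (patch off the raster,
#' nodata climate pixel) are dropped and counted. Output order is sorted by
#' anchor id for determinism.
#'
#' @param labels indexed `sdm_labels` (after [expand_ranks()]).
#' @param imagery imagery raster, or `NULL` for climate-only models.
#' @param climate climate raster, or `NULL` for image-only models.
#' @param normalizer `sdm_normalizer` (required with `climate`).
#' @param completeness optional named vector of per-anchor completeness in
#'   (0, 1]; default 1 for every anchor.
#' @param patch_px image patch side length, pixels.
#' @return an `sdm_samples` object: list with `anchor_id`, `x`, `y`, `images`
#'   (`(4, patch_px, patch_px, N)` array or `NULL`), `climate` (`B x N` matrix
#'   or `NULL`), `completeness` (length N), `targets` (lists of 1-based index
#'   vectors at ranks species/genus/family), `index`, `n_dropped`.
#' @export
assemble_samples <- function(labels, imagery = NULL, climate = NULL,
                             normalizer = NULL, completeness = NULL,
                             patch_px = 256) {
  stopifnot(!is.null(labels$index))
  ord <- order(labels$anchors$anchor_id)
  ids <- labels$anchors$anchor_id[ord]
  xs <- labels$anchors$x[ord]; ys <- labels$anchors$y[ord]
  n <- length(ids)
  imgs <- vector("list", n); clims <- vector("list", n)
  ok <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!is.null(imagery)) {
      p <- extract_image_patch(imagery, xs[i], ys[i], patch_px)
      if (is.null(p)) { ok[i] <- FALSE; next }
      imgs[[i]] <- p
    }
    if (!is.null(climate)) {
      stopifnot(!is.null(normalizer))
      v <- extract_climate_vector(climate, normalizer, xs[i], ys[i])
      if (is.null(v)) { ok[i] <- FALSE; next }
      clims[[i]] <- v
    }
  }
  if (!any(ok)) stop("assemble_samples: no anchor has all components", call. = FALSE)
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    message(sprintf("assemble_samples: dropped %d of %d anchors missing imagery/climate", n_dropped, n))
  }
  keep <- which(ok)
  comp <- rep(1, length(keep))
  if (!is.null(completeness)) {
    m <- completeness[match(ids[keep], names(completeness))]
    comp <- unname(ifelse(is.na(m), 1, m))
  }
  images <- NULL
  if (!is.null(imagery)) {
    images <- array(0, c(dim(imgs[[keep[1]]]), length(keep)))
    for (j in seq_along(keep)) images[, , , j] <- imgs[[keep[j]]]
  }
  clim_mat <- NULL
  if (!is.null(climate)) {
    clim_mat <- vapply(keep, function(i) clims[[i]], numeric(length(normalizer$mean)))
    clim_mat <- matrix(clim_mat, ncol = length(keep))
  }
  sel <- ord[keep]
  structure(
    list(anchor_id = ids[keep], x = xs[keep], y = ys[keep],
         images = images, climate = clim_mat, completeness = comp,
         targets = list(species = labels$species_idx[sel],
                        genus = labels$genus_idx[sel],
                        family = labels$family_idx[sel]),
         index = labels$index, n_dropped = n_dropped),
    class = "sdm_samples")
}

#' @export
print.sdm_samples <- function(x, ...) {
  cat(sprintf("<sdm_samples> %d anchors | %s | %s | %d species\n",
              length(x$anchor_id),
              if (is.null(x$images)) "no imagery" else paste(dim(x$images)[1:3], collapse = "x"),
              if (is.null(x$climate)) "no climate" else sprintf("%d climate bands", nrow(x$climate)),
              length(x$index$species)))
  invisible(x)
}

#' Subset samples by anchor id
#' @param samples an `sdm_samples` object.
#' @param ids anchor ids to keep.
#' @return the subset `sdm_samples`.
#' @export
subset_samples <- function(samples, ids) {
  sel <- which(samples$anchor_id %in% ids)
  out <- samples
  out$anchor_id <- samples$anchor_id[sel]
  out$x <- samples$x[sel]; out$y <- samples$y[sel]
  if (!is.null(samples$images)) out$images <- samples$images[, , , sel, drop = FALSE]
  if (!is.null(samples$climate)) out$climate <- samples$climate[, sel, drop = FALSE]
  out$completeness <- samples$completeness[sel]
  out$targets <- lapply(samples$targets, function(t) t[sel])
  out
}
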