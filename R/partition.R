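#' Buffered uniform train/test split
#'
#' Samples candidate test anchors uniformly at random (seeded). A candidate is
#' accepted only when its nearest *non-overlapping* neighbor — the nearest
#' anchor farther than `overlap_radius_m` away — lies more than
#' `exclusion_radius_m` away, so no training image shares climate-pixel-scale
#' surroundings with a test image. Every anchor within `overlap_radius_m` of an
#' accepted candidate is moved to the test set with it (overlapping image
#' footprints must not straddle the split). Sampling stops once the test set
#' reaches `test_fraction` of the anchors or candidates are exhausted (with a
#' warning).
#'
#' @param labels an `sdm_labels` object.
#' @param test_fraction target test fraction in (0, 1). The default mirrors a
#'   realized statewide split fraction of 1.88%.
#' @param exclusion_radius_m leakage exclusion radius, meters.
#' @param overlap_radius_m image-footprint overlap radius, meters.
#' @param seed integer seed for candidate order.
#' @return an `sdm_split` object: list with `kind`, `train_ids`, `test_ids`,
#'   `exclusion_radius_m`, `overlap_radius_m`.
#' @export
uniform_split <- function(labels, test_fraction = 0.0188,
                          exclusion_radius_m = 1300, overlap_radius_m = 256,
                          seed = 1) {
  a <- labels$anchors
  n <- nrow(a)
  stopifnot(n >= 2, test_fraction > 0, test_fraction < 1)
  set.seed(seed)
  target <- max(1L, ceiling(test_fraction * n))
  in_test <- logical(n)
  order_cand <- sample.int(n)
  excl2 <- exclusion_radius_m^2
  over2 <- overlap_radius_m^2
  n_test <- 0L
  for (i in order_cand) {
    if (n_test >= target) break
    if (in_test[i]) next
    d2 <- (a$x - a$x[i])^2 + (a$y - a$y[i])^2
    d2[i] <- Inf
    nonover <- d2 > over2
    if (any(nonover) && min(d2[nonover]) <= excl2) next
    grp <- which(d2 <= over2 & !in_test)
    in_test[i] <- TRUE
    in_test[grp] <- TRUE
    n_test <- sum(in_test)
  }
  if (n_test < target) {
    warning(sprintf("uniform_split: candidate pool exhausted at %d of %d targeted test anchors",
                    n_test, target), call. = FALSE)
  }
  structure(
    list(kind = "uniform",
         train_ids = a$anchor_id[!in_test],
         test_ids = a$anchor_id[in_test],
         exclusion_radius_m = exclusion_radius_m,
         overlap_radius_m = overlap_radius_m,
         block_index = NULL),
    class = "sdm_split")
}

#' Latitudinal block cross-validation folds
#'
#' Partitions anchors into `n_bands` consecutive one-degree latitude bands
#' (half-open `[lo, hi)` intervals snapped to integer degrees covering the
#' data extent; anchors above the last edge fall in the last band). Fold `k`
#' tests on band `k` and trains on anchors outside the band and farther than
#' `exclusion_radius_m` from the band's edges (latitude distance converted to
#' meters in the projected CRS).
#'
#' @param labels an `sdm_labels` object.
#' @param n_bands number of one-degree bands.
#' @param exclusion_radius_m leakage exclusion radius, meters.
#' @return list of `sdm_split` objects, one per band, each with
#'   `block_index` and `band` (degree interval) set.
#' @export
latitudinal_folds <- function(labels, n_bands = 10, exclusion_radius_m = 1300) {
  a <- labels$anchors
  lat <- latitude_of(a$x, a$y, labels$crs)
  lo0 <- floor(min(lat))
  edges <- lo0 + 0:n_bands
  band <- pmin(pmax(floor(lat) - lo0 + 1, 1L), n_bands)
  folds <- vector("list", n_bands)
  excl_deg <- exclusion_radius_m / .M_PER_DEG_LAT
  for (k in seq_len(n_bands)) {
    test <- band == k
    if (!any(test)) {
      warning(sprintf("latitudinal_folds: band %d is empty", k), call. = FALSE)
    }
    # distance from an outside anchor to the band's latitude envelope
    lo <- edges[k]; hi <- edges[k + 1]
    d_deg <- pmax(lo - lat, lat - hi, 0)
    train <- !test & d_deg > excl_deg
    folds[[k]] <- structure(
      list(kind = "block",
           train_ids = a$anchor_id[train],
           test_ids = a$anchor_id[test],
           exclusion_radius_m = exclusion_radius_m,
           overlap_radius_m = NULL,
           block_index = k,
           band = c(lo, hi)),
      class = "sdm_split")
  }
  folds
}

#' @export
print.sdm_split <- function(x, ...) {
  cat(sprintf("<sdm_split:%s> train %d | test %d | exclusion %g m%s\n",
              x$kind, length(x$train_ids), length(x$test_ids),
              x$exclusion_radius_m,
              if (!is.null(x$block_index)) sprintf(" | band %d", x$block_index) else ""))
  invisible(x)
}

#' Serialize a split to JSON
#' @param split an `sdm_split`.
#' @param path output path; `read_split()` reads it back.
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(
    list(kind = split$kind, train = split$train_ids, test = split$test_ids,
         exclusion_radius_m = split$exclusion_radius_m,
         overlap_radius_m = split$overlap_radius_m,
         block_index = split$block_index),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(kind = j$kind, train_ids = j$train, test_ids = j$test,
         exclusion_radius_m = j$exclusion_radius_m,
         overlap_radius_m = j$overlap_radius_m,
         block_index = j$block_index),
    class = "sdm_split")
}
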