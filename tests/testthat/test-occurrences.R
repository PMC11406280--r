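test_that("read_occurrences parses, validates and logs dropped rows", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(record_id = c("a", "b", "c"),
                       species = c("sp1", "sp2", "sp1"),
                       x = c(0, 100, 200), y = c(0, 0, 50)),
            f, row.names = FALSE)
  occ <- suppressWarnings(read_occurrences(f))
  expect_equal(nrow(occ), 3)
  expect_setequal(names(occ)[1:4], c("record_id", "species", "x", "y"))

  write.csv(data.frame(record_id = c("a", "b", "c"),
                       species = c("sp1", "", "sp1"),
                       x = c(0, 100, NA), y = c(0, 0, 50)),
            f, row.names = FALSE)
  expect_message(occ <- suppressWarnings(read_occurrences(f)),
                 "dropped 2 of 3")
  expect_equal(occ$record_id, "a")

  # coordinate-uncertainty filter applies when the column exists
  write.csv(data.frame(record_id = c("a", "b"), species = c("sp1", "sp1"),
                       x = c(0, 10), y = c(0, 0),
                       coord_uncertainty_m = c(50, 500)),
            f, row.names = FALSE)
  occ <- read_occurrences(f)
  expect_equal(occ$record_id, "a")

  expect_error(suppressWarnings(read_occurrences(tempfile())), "not found")
  write.csv(data.frame(record_id = c("a", "a"), species = "sp1",
                       x = 0, y = 0), f, row.names = FALSE)
  expect_error(suppressWarnings(read_occurrences(f)), "not unique")
})

test_that("lon/lat input is reprojected to meters and round-trips within 1 m", {
  f <- tempfile(fileext = ".csv")
  lon <- c(-122.4, -121.9, -120.2)
  lat <- c(37.8, 38.6, 39.9)
  write.csv(data.frame(record_id = c("a", "b", "c"), species = "sp1",
                       lon = lon, lat = lat, coord_uncertainty_m = 10),
            f, row.names = FALSE)
  occ <- read_occurrences(f, crs = "EPSG:4326")
  crs <- attr(occ, "crs")
  expect_match(crs, "^LTM:")
  back <- lonlat_from_xy(occ$x, occ$y, crs)
  # 1e-5 degrees is ~1 m
  expect_lt(max(abs(back[, "lon"] - lon)), 1e-5)
  expect_lt(max(abs(back[, "lat"] - lat)), 1e-5)
  # sanity: ~88 km between first two points on the ground
  d <- sqrt(diff(occ$x[1:2])^2 + diff(occ$y[1:2])^2)
  expect_gt(d, 7e4); expect_lt(d, 1.2e5)
  expect_error(read_occurrences(f, crs = "EPSG:99999"), "required column")
})

test_that("dedup keeps the first record and enforces the radius per species", {
  occ <- make_occ(c("sp1", "sp1"), c(0, 0), c(0, 100))
  expect_equal(dedup_within_radius(occ, 150)$record_id, "r001")

  occ <- make_occ(c("sp1", "sp2"), c(0, 0), c(0, 100))
  expect_equal(nrow(dedup_within_radius(occ, 150)), 2)

  # greedy pass: 100 m drops the second, 190 m from the first keeps the third
  occ <- make_occ(rep("sp1", 3), c(0, 0, 0), c(0, 100, 190))
  kept <- dedup_within_radius(occ, 150)
  expect_equal(kept$y, c(0, 190))
})

test_that("dedup is idempotent, non-increasing, and separates kept points", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 120
    occ <- make_occ(sample(paste0("sp", 1:4), n, replace = TRUE),
                    runif(n, 0, 2000), runif(n, 0, 2000))
    d1 <- dedup_within_radius(occ, 150)
    d2 <- dedup_within_radius(d1, 150)
    expect_identical(d1$record_id, d2$record_id)
    expect_lte(nrow(d1), nrow(occ))
    for (sp in unique(d1$species)) {
      pts <- d1[d1$species == sp, ]
      if (nrow(pts) > 1) {
        dm <- as.matrix(dist(pts[, c("x", "y")]))
        expect_gt(min(dm[upper.tri(dm)]), 150)
      }
    }
  }
})

test_that("spatially confined species are removed by the centroid rule", {
  # max distance to centroid 200 <= 256: removed
  occ <- make_occ(c("spA", "spA"), c(0, 0), c(0, 400))
  expect_equal(nrow(drop_confined_species(occ, 256)), 0)
  # max distance 300 > 256: kept
  occ <- make_occ(c("spA", "spA"), c(0, 0), c(0, 600))
  expect_equal(nrow(drop_confined_species(occ, 256)), 2)
  # single occurrence is trivially confined
  occ <- make_occ(c("spA", "spB", "spB"), c(0, 0, 0), c(0, 0, 600))
  out <- drop_confined_species(occ, 256)
  expect_setequal(out$species, "spB")
})

test_that("clip keeps points inside boundary and all raster extents", {
  boundary <- cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000))
  clim <- new_raster(matrix(1, 5, 5), 0, 500, 100, "local")  # covers y in [0,500]
  occ <- make_occ(c("sp1", "sp1", "sp1"), c(100, 100, 2000), c(100, 800, 100))
  out <- clip_to_extent(occ, boundary, list(clim))
  expect_equal(out$record_id, "r001")          # inside both
  # r002 inside boundary but outside climate raster -> dropped
  out2 <- clip_to_extent(occ, boundary)
  expect_setequal(out2$record_id, c("r001", "r002"))
  # a point exactly on the boundary edge is kept (closed polygon)
  edge <- make_occ("sp1", 0, 500)
  expect_equal(nrow(clip_to_extent(edge, boundary)), 1)
  expect_warning(clip_to_extent(make_occ("sp1", -5000, -5000), boundary),
                 "no occurrences")
})

test_that("minimum-count filter runs on label memberships", {
  # spA is isolated with 1 membership; spB collects 3
  occ <- make_occ(c("spA", "spB", "spB", "spB"),
                  c(0, 1000, 5000, 10000), c(0, 0, 0, 0))
  lab <- neighbor_impute(occ, 256)
  counts <- table(unlist(lab$species))
  expect_equal(unname(counts[["spA"]]), 1)
  expect_equal(unname(counts[["spB"]]), 3)

  out <- filter_min_count(lab, 3)
  expect_setequal(unique(unlist(out$species)), "spB")
  expect_equal(nrow(out$anchors), 3)  # the spA-only anchor drops with it

  # boundary: a species with exactly min_count memberships is kept
  kept <- filter_min_count(lab, 1)
  expect_true("spA" %in% unlist(kept$species))
  expect_false("spA" %in% unlist(filter_min_count(lab, 2)$species))
  # min_count = 1 is the identity
  expect_identical(kept$species, lab$species)
  expect_error(filter_min_count(lab, 1000), "below min_count")
})
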