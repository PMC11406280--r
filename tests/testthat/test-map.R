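test_that("strided maps have the floor((H - window)/stride) + 1 geometry", {
  cfg <- tiny_config(S = 4, B = 3, patch = 16)
  m <- build_fused_model(cfg)
  m$index <- list(species = paste0("sp", 1:4))
  clim <- make_climate(40, bands = 3, res = 10)  # covers the imagery extent
  img <- make_imagery(82, res = 1, seed = 3)
  pm <- predict_map(m, img, clim, fit_climate_normalizer(clim),
                    window_px = 16, stride_px = 25)
  expect_equal(dim(pm$probs), c(4, 3, 3))   # floor((82-16)/25)+1 = 3
  expect_equal(pm$res, 25)                  # stride x 1 m = output spacing
  pm1 <- predict_map(m, make_imagery(16, res = 1), clim,
                     fit_climate_normalizer(clim), window_px = 16,
                     stride_px = 16)
  expect_equal(dim(pm1$probs), c(4, 1, 1))  # window-sized raster: single cell
  expect_true(all(pm$probs > 0 & pm$probs < 1))
  # first output cell is georeferenced to the first window's center
  expect_equal(pm$xmin, img$xmin + 8)
  expect_error(predict_map(m, make_imagery(8), clim,
                           fit_climate_normalizer(clim), window_px = 16,
                           stride_px = 4),
               "smaller than the prediction window")
})

test_that("spatial community change matches hand-computed neighborhoods", {
  # constant map: zero everywhere
  P <- array(0.4, c(3, 5, 5))
  expect_true(all(spatial_community_change(P) == 0))
  # 3x3 map, center differs by 1 in one species: center value 1.0
  P2 <- array(0, c(2, 3, 3))
  P2[1, 2, 2] <- 1
  scc <- spatial_community_change(P2)
  expect_equal(scc[2, 2], 1.0)
  # each border neighbor of the center sees ||delta|| = 1 once among its
  # existing neighbors (corners have 3, edges 5)
  expect_equal(scc[1, 1], 1 / 3)
  expect_equal(scc[1, 2], 1 / 5)
  # two vertical halves differing by delta in one species: a cell beside the
  # edge has 3 of its 8 neighbors across it -> 3 delta / 8
  delta <- 0.25
  P3 <- array(0, c(2, 4, 4))
  P3[1, , 3:4] <- delta
  scc3 <- spatial_community_change(P3)
  expect_equal(scc3[2, 2], 3 * delta / 8)
  expect_equal(scc3[2, 3], 3 * delta / 8)
  # single-cell map warns and returns zero
  expect_warning(z <- spatial_community_change(array(1, c(2, 1, 1))),
                 "single-cell")
  expect_equal(z, matrix(0, 1, 1))
})

test_that("spatial change commutes with species permutation", {
  set.seed(13)
  P <- array(runif(5 * 6 * 6), c(5, 6, 6))
  expect_equal(spatial_community_change(P),
               spatial_community_change(P[c(3, 5, 1, 2, 4), , ]),
               tolerance = 1e-12)
})

test_that("temporal community change is a per-cell Euclidean distance", {
  P <- array(runif(3 * 4 * 4), c(3, 4, 4))
  expect_true(all(temporal_community_change(P, P) == 0))
  # all probabilities shift by delta: delta * sqrt(S) per cell
  delta <- 0.2
  expect_equal(temporal_community_change(P, P + delta),
               matrix(delta * sqrt(3), 4, 4), tolerance = 1e-12)
  # S = 2 worked example
  A <- array(c(0.9, 0.1), c(2, 1, 1))
  B <- array(c(0.1, 0.9), c(2, 1, 1))
  expect_equal(temporal_community_change(A, B)[1, 1], sqrt(0.64 + 0.64),
               tolerance = 1e-9)
  # symmetry and per-cell triangle inequality
  Q <- array(runif(3 * 4 * 4), c(3, 4, 4))
  R_ <- array(runif(3 * 4 * 4), c(3, 4, 4))
  expect_equal(temporal_community_change(P, Q), temporal_community_change(Q, P))
  expect_true(all(temporal_community_change(P, R_) <=
                    temporal_community_change(P, Q) +
                    temporal_community_change(Q, R_) + 1e-12))
  expect_error(temporal_community_change(P, array(0, c(3, 5, 5))), "mismatched")
})

test_that("raw-imagery change baselines standardize, block, and compare", {
  img <- make_imagery(32, res = 8, seed = 21)   # 256 m = 32 px per... 4 px/cell
  # identical rasters, temporal mode: zero
  expect_true(all(raw_image_change(img, img, "temporal", cell_m = 64) == 0))
  # constant raster, spatial mode: zero
  const <- new_raster(array(0.5, c(16, 16, 4)), 0, 128, 8, "local")
  expect_true(all(raw_image_change(const, mode = "spatial", cell_m = 32) == 0))
  # toy: verify the blocked temporal distance against direct arithmetic
  av <- array(rep(c(0, 1), each = 8), c(4, 4, 2))
  bv <- av; bv[1:2, 1:2, 1] <- av[1:2, 1:2, 1] + 0.5
  ra <- new_raster(av, 0, 8, 2, "local")
  rb <- new_raster(bv, 0, 8, 2, "local")
  out <- raw_image_change(ra, rb, "temporal", cell_m = 4)
  zf <- function(m) if (sd(as.numeric(m)) > 0) (m - mean(m)) / sd(as.numeric(m)) else m * 0
  blk <- function(m) rbind(c(mean(m[1:2, 1:2]), mean(m[1:2, 3:4])),
                           c(mean(m[3:4, 1:2]), mean(m[3:4, 3:4])))
  manual <- sqrt((blk(zf(av[, , 1])) - blk(zf(bv[, , 1])))^2 +
                   (blk(zf(av[, , 2])) - blk(zf(bv[, , 2])))^2)
  expect_equal(out, manual, tolerance = 1e-9)
  expect_error(raw_image_change(ra, new_raster(bv, 10, 8, 2, "local"),
                                "temporal", 4),
               "co-registered")
})

test_that("prediction maps serialize with species bands and sidecar metadata", {
  cfg <- tiny_config(S = 3, B = 3, patch = 16)
  m <- build_fused_model(cfg)
  m$index <- list(species = c("oak", "pine", "sage"))
  clim <- make_climate(10, bands = 3, res = 10)
  pm <- predict_map(m, make_imagery(48), clim, fit_climate_normalizer(clim),
                    window_px = 16, stride_px = 16)
  f <- file.path(tempdir(), "map.tif")
  write_prediction_map(pm, f)
  meta <- jsonlite::read_json(paste0(f, ".json"), simplifyVector = TRUE)
  expect_equal(meta$band_names, c("oak", "pine", "sage"))
  expect_equal(meta$stride_px, 16)
  back <- read_raster(f)
  expect_equal(aperm(back$values, c(3, 1, 2)), pm$probs, tolerance = 1e-6)
})
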