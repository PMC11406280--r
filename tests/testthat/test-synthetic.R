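test_that("worlds are bit-for-bit reproducible from their seed", {
  w1 <- generate_world(seed = 5, R = 12, C = 12, S = 6, B = 4, m = 2)
  w2 <- generate_world(seed = 5, R = 12, C = 12, S = 6, B = 4, m = 2)
  expect_identical(w1$env, w2$env)
  expect_identical(w1$imagery, w2$imagery)
  expect_identical(w1$presence, w2$presence)
  w3 <- generate_world(seed = 6, R = 12, C = 12, S = 6, B = 4, m = 2)
  expect_false(identical(w1$presence, w3$presence))
})

test_that("species prevalences are calibrated and never empty", {
  w <- generate_world(seed = 9, R = 30, C = 30, S = 20, B = 5, m = 2)
  prev <- apply(w$presence, 1, mean)
  expect_true(all(prev > 0))
  expect_true(all(prev >= 0.01 & prev <= 0.55))
  # species without land-cover affinity depend only on the environment
  no_lc <- which(!w$niche$uses_landcover)
  expect_true(all(w$niche$a[no_lc, ] == 0))
})

test_that("the truth raster matches a brute-force niche re-evaluation", {
  w <- generate_world(seed = 3, R = 10, C = 10, S = 5, B = 4, m = 2)
  for (s in c(1, 5)) {
    r <- true_presence_map(w, s)
    expect_equal(mean(r$values), mean(w$presence[s, , ]))
    manual <- matrix(0, w$R, w$C)
    for (i in seq_len(w$R)) for (j in seq_len(w$C)) {
      lin <- sum(w$niche$w[s, ] * w$env[, i, j]) +
        w$niche$a[s, w$landcover[i, j]] + w$niche$b[s]
      manual[i, j] <- as.integer(plogis(lin) > w$niche$u[s])
    }
    expect_equal(matrix(r$values[, , 1], w$R, w$C), manual)
  }
  expect_error(true_presence_map(w, 99), "invalid species")
  expect_error(true_presence_map(w, "nope"), "invalid species")
})

test_that("occurrence simulation respects detectability and effort bias", {
  w <- generate_world(seed = 8, R = 20, C = 20, S = 10, B = 4, m = 2)
  # empty draw
  expect_equal(nrow(simulate_occurrences(w, 0, seed = 1)), 0)
  # detectability ~ 0.2: realized completeness near 0.2 on average
  set.seed(0)
  occ <- simulate_occurrences(w, 4000, detectability = 0.2, seed = 2)
  pres <- matrix(w$presence, w$S, w$R * w$C)
  # effort-weighted mean richness of the sampled cell distribution
  eff <- as.numeric(w$effort)
  expected <- sum(colSums(pres) * eff) / sum(eff)
  realized <- nrow(occ) / 4000              # mean recorded per visit
  expect_lt(abs(realized / expected - 0.2), 0.03)
  expect_setequal(names(occ)[1:4], c("record_id", "species", "x", "y"))
  expect_false(anyDuplicated(occ$record_id) > 0)
  # full detectability, huge n: every cell's observed set converges to truth
  occ2 <- simulate_occurrences(w, 6000, detectability = 1, seed = 3)
  cell <- cbind(floor((w$ymax - occ2$y) / w$cell_m) + 1,
                floor(occ2$x / w$cell_m) + 1)
  visited <- unique(cell)
  miss <- 0
  for (k in sample(nrow(visited), 50)) {
    truth_sp <- w$species[which(w$presence[, visited[k, 1], visited[k, 2]] == 1)]
    seen_sp <- unique(occ2$species[cell[, 1] == visited[k, 1] &
                                     cell[, 2] == visited[k, 2]])
    miss <- miss + length(setdiff(truth_sp, seen_sp))
  }
  expect_equal(miss, 0)
  # effort concentrated in one quadrant: >= 90% of visits land there, and
  # the realized fraction tracks the multinomial expectation
  wq <- generate_world(seed = 12, R = 20, C = 20, S = 6, B = 4, m = 2,
                       effort_quadrant = 1, effort_quadrant_weight = 200)
  occq <- simulate_occurrences(wq, 2000, detectability = 1, seed = 4)
  in_quad <- occq$x <= 10 * wq$cell_m & occq$y >= 10 * wq$cell_m
  expect_gte(mean(in_quad), 0.9)
  quad_mask <- matrix(FALSE, 20, 20); quad_mask[1:10, 1:10] <- TRUE
  expected_frac <- sum(wq$effort[quad_mask]) / sum(wq$effort)
  # weight visits by records per visit being roughly cell-independent
  expect_lt(abs(mean(in_quad) - expected_frac), 0.08)
})

test_that("synthetic taxonomy groups species 4-to-1 into genera and families", {
  tax <- synthetic_taxonomy(sprintf("species_%03d", 1:20))
  expect_equal(nrow(tax), 20)
  expect_equal(length(unique(tax$genus)), 5)
  expect_equal(length(unique(tax$family)), 2)
  expect_silent(read_taxonomy(tax))
})

test_that("disturbance alters imagery, communities and probabilities only inside", {
  w <- generate_world(seed = 88, R = 24, C = 24, S = 10, B = 4, m = 4)
  wd <- disturb_world(w, 6:12, 8:14)
  expect_false(identical(w$landcover[6:12, 8:14], wd$landcover[6:12, 8:14]))
  expect_identical(w$landcover[-(6:12), ], wd$landcover[-(6:12), ])
  tcc <- temporal_community_change(true_probability_map(w),
                                   true_probability_map(wd))
  expect_true(all(tcc[-(6:12), ] == 0))
  expect_gt(mean(tcc[6:12, 8:14] > 0), 0.9)
})

test_that("fused models dominate single-modality models on their blind side", {
  # half the species are land-cover driven (invisible to climate), half are
  # climate driven (invisible to imagery); medians over three seeds
  res <- vapply(c(201, 301, 401), function(seed) {
    cw <- curated_world(seed = seed)
    smp <- suppressMessages(assemble_samples(cw$labels, cw$rasters$imagery,
                                             cw$rasters$climate,
                                             cw$normalizer, patch_px = 16))
    x0 <- 30 * cw$world$cell_m
    sp <- structure(list(kind = "block",
                         train_ids = smp$anchor_id[smp$x < x0 - 1300],
                         test_ids = smp$anchor_id[smp$x > x0],
                         exclusion_radius_m = 1300), class = "sdm_split")
    cfg <- model_config(S = length(smp$index$species),
                        G = length(smp$index$genus),
                        F = length(smp$index$family), climate_dim = 6,
                        mlp_hidden = c(64, 64, 128, 128), encoder_width = 8,
                        encoder_depth = 2, patch_px = 16, fusion_dim = 64,
                        seed = 5)
    tc <- train_config(epochs = 8, learning_rate = 2e-3, batch_size = 64,
                       seed = 11)
    aucs <- function(m) map_truth_aucs(m, cw, col_min = 30)
    af <- aucs(train_model(build_fused_model(cfg), smp, sp, tc))
    ac <- aucs(train_model(build_climate_mlp(cfg), smp, sp, tc))
    ai <- aucs(train_model(build_image_encoder(cfg), smp, sp, tc))
    lc <- cw$world$niche$uses_landcover[match(smp$index$species,
                                              cw$world$species)]
    c(fused_lc = median(af[lc], na.rm = TRUE),
      clim_lc = median(ac[lc], na.rm = TRUE),
      fused_env = median(af[!lc], na.rm = TRUE),
      img_env = median(ai[!lc], na.rm = TRUE))
  }, c(fused_lc = 0, clim_lc = 0, fused_env = 0, img_env = 0))
  expect_gte(median(res["fused_lc", ]), median(res["clim_lc", ]))
  expect_gte(median(res["fused_env", ]), median(res["img_env", ]))
})
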