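test_that("location completeness is a capped richness-quantile ratio", {
  # 30 isolated clusters of 4 distinct species, one cluster of 2:
  # n_ref (95% quantile) = 4, so the small cluster gets c = 0.5
  xs <- ys <- c(); sp <- c()
  for (k in 1:30) {
    xs <- c(xs, rep(k * 10000, 4)); ys <- c(ys, c(0, 10, 20, 30))
    sp <- c(sp, paste0("sp", k, "_", 1:4))
  }
  xs <- c(xs, 5e6, 5e6); ys <- c(ys, c(0, 10)); sp <- c(sp, "spx1", "spx2")
  lab <- neighbor_impute(make_occ(sp, xs, ys), 256)
  cc <- estimate_location_completeness(lab, radius_m = 256)
  expect_equal(unname(cc[121]), 0.5)
  # anchors in the richest neighborhoods are capped at 1
  expect_equal(unname(cc[1]), 1)
  expect_true(all(cc > 0 & cc <= 1))

  # all anchors with identical richness: completeness 1 everywhere
  lab2 <- neighbor_impute(make_occ(c("a", "b", "c"),
                                   c(0, 1e5, 2e5), c(0, 0, 0)), 256)
  expect_true(all(estimate_location_completeness(lab2) == 1))
})

test_that("zero learning rate leaves weights unchanged with a flat history", {
  cw <- curated_world()
  smp <- suppressMessages(assemble_samples(cw$labels, NULL, cw$rasters$climate,
                                           cw$normalizer))
  ids <- smp$anchor_id
  sp <- structure(list(kind = "uniform", train_ids = ids[-(1:50)],
                       test_ids = ids[1:50], exclusion_radius_m = 0),
                  class = "sdm_split")
  cfg <- tiny_config(S = length(smp$index$species),
                     G = length(smp$index$genus),
                     F = length(smp$index$family), B = 6)
  m0 <- build_climate_mlp(cfg)
  before <- fusedsdm:::model_params(m0)
  m1 <- train_model(m0, smp, sp, train_config(epochs = 2, learning_rate = 0,
                                              batch_size = 128, seed = 3))
  expect_identical(fusedsdm:::model_params(m1), before)
  # flat up to dropout-mask sampling noise in the per-batch averages
  h <- m1$history$epochs
  expect_equal(h$loss[1], h$loss[2], tolerance = 1e-2)
  expect_equal(h$monitor_auc[1], h$monitor_auc[2], tolerance = 1e-9)
})

test_that("training reduces the loss and is reproducible under a fixed seed", {
  cw <- curated_world()
  smp <- suppressMessages(assemble_samples(cw$labels, NULL, cw$rasters$climate,
                                           cw$normalizer))
  ids <- smp$anchor_id
  sp <- structure(list(kind = "uniform", train_ids = ids[-(1:100)],
                       test_ids = ids[1:100], exclusion_radius_m = 0),
                  class = "sdm_split")
  cfg <- tiny_config(S = length(smp$index$species),
                     G = length(smp$index$genus),
                     F = length(smp$index$family), B = 6)
  tc <- train_config(epochs = 3, learning_rate = 3e-3, batch_size = 64, seed = 7)
  m1 <- train_model(build_climate_mlp(cfg), smp, sp, tc)
  h <- m1$history$epochs
  expect_lt(h$loss[3], h$loss[1])
  expect_true(m1$trained)
  # selected epoch maximizes the monitored AUC
  expect_equal(m1$history$selected_epoch, which.max(h$monitor_auc))
  # same seed, same data: identical history
  m2 <- train_model(build_climate_mlp(cfg), smp, sp, tc)
  expect_identical(m1$history$epochs, m2$history$epochs)
  expect_identical(fusedsdm:::model_params(m1), fusedsdm:::model_params(m2))
  expect_error(train_model(build_climate_mlp(cfg), smp,
                           structure(list(train_ids = character(0),
                                          test_ids = ids[1:5]),
                                     class = "sdm_split"), tc),
               "empty training set")
})

test_that("sampling-aware loss matches or beats plain BCE under biased sampling", {
  # strongly biased effort (one quadrant 25x) and low detectability, in a
  # many-species regime where within-observation class imbalance matters
  run <- function(seed) {
    cw <- curated_world(seed = seed, S = 32, n_occ = 2500, det = 0.3,
                        quadrant = 1)
    smp <- suppressMessages(assemble_samples(cw$labels, NULL,
                                             cw$rasters$climate,
                                             cw$normalizer))
    comp <- estimate_location_completeness(cw$labels)
    smp_sa <- smp
    smp_sa$completeness <- unname(comp[match(smp$anchor_id, names(comp))])
    ids <- smp$anchor_id
    set.seed(seed)
    test <- sample(ids, 150)
    sp <- structure(list(kind = "uniform", train_ids = setdiff(ids, test),
                         test_ids = test, exclusion_radius_m = 0),
                    class = "sdm_split")
    cfg <- model_config(S = length(smp$index$species),
                        G = length(smp$index$genus),
                        F = length(smp$index$family), climate_dim = 6,
                        mlp_hidden = c(64, 64, 128, 128), seed = 5)
    truth_auc <- function(m) {
      w <- cw$world
      clim <- (matrix(w$env, w$B, w$R * w$C) - cw$normalizer$mean) /
        cw$normalizer$sd
      p <- predict_probabilities(m, list(climate = clim))
      median(vapply(seq_len(ncol(p)), function(s) {
        si <- match(colnames(p)[s], w$species)
        auc_roc(p[, s], as.numeric(w$presence[si, , ]))
      }, 0.0), na.rm = TRUE)
    }
    msa <- train_model(build_climate_mlp(cfg), smp_sa, sp,
                       train_config(epochs = 8, learning_rate = 3e-3,
                                    batch_size = 64,
                                    loss_name = "sampling_aware_bce", seed = 11))
    mb <- train_model(build_climate_mlp(cfg), smp, sp,
                      train_config(epochs = 8, learning_rate = 3e-3,
                                   batch_size = 64, loss_name = "bce",
                                   seed = 11))
    c(sa = truth_auc(msa), bce = truth_auc(mb))
  }
  res <- t(vapply(c(11, 22, 33, 44, 55), run, c(sa = 0, bce = 0)))
  expect_gte(median(res[, "sa"]), median(res[, "bce"]))
})

test_that("the learning-rate sweep covers half-decade steps across the range", {
  g <- learning_rate_grid()
  expect_equal(g[1], 5e-6)
  expect_lte(max(g), 1e-1)
  expect_equal(unique(round(diff(log10(g)), 9)), 0.5)
  expect_gt(max(g), 1e-2)
})
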