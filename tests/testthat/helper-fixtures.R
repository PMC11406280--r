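# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except files the tests themselves write to tempdir().

make_occ <- function(species, x, y, ids = NULL) {
  df <- data.frame(
    record_id = if (is.null(ids)) sprintf("r%03d", seq_along(species)) else ids,
    species = species, x = x, y = y, stringsAsFactors = FALSE)
  attr(df, "crs") <- "local"
  df
}

# A small random 4-band imagery raster.
make_imagery <- function(n = 64, res = 1, seed = 1, xmin = 0, ymax = n * res) {
  set.seed(seed)
  new_raster(array(runif(n * n * 4), c(n, n, 4)), xmin, ymax, res, "local",
             c("r", "g", "b", "nir"))
}

# Climate raster with known per-band values.
make_climate <- function(n = 8, bands = 3, res = 100, seed = 2) {
  set.seed(seed)
  new_raster(array(rnorm(n * n * bands, mean = 10, sd = 4), c(n, n, bands)),
             0, n * res, res, "local")
}

# Random multilabel targets: n rows, s species, each row npos positives,
# guaranteeing every row >= 1 positive.
make_targets <- function(n, s, npos = 3, seed = 1) {
  set.seed(seed)
  t_ <- matrix(0, n, s)
  for (i in seq_len(n)) t_[i, sample.int(s, npos)] <- 1
  t_
}

# Desk-scale model config used across model/training tests.
tiny_config <- function(S, G = max(1, ceiling(S / 4)), F = max(1, ceiling(S / 16)),
                        B = 6, patch = 16, seed = 5) {
  model_config(S = S, G = G, F = F, climate_dim = B,
               mlp_hidden = c(16, 16, 24, 24), mlp_dropout = 0.25,
               encoder_width = 4, encoder_depth = 2, patch_px = patch,
               fusion_dim = 16, seed = seed)
}

# Cached curated pipeline on a small world, shared by training/synthetic
# tests to avoid regenerating identical fixtures.
.world_cache <- new.env(parent = emptyenv())

curated_world <- function(seed = 101, S = 12, n_occ = 3500, det = 0.6,
                          quadrant = NULL) {
  key <- paste(seed, S, n_occ, det, paste(quadrant, collapse = ""), sep = "_")
  if (!is.null(.world_cache[[key]])) return(.world_cache[[key]])
  w <- generate_world(seed = seed, R = 40, C = 40, S = S, B = 6, m = 8,
                      cell_m = 256, effort_quadrant = quadrant,
                      effort_quadrant_weight = if (is.null(quadrant)) 20 else 25)
  occ <- simulate_occurrences(w, n_occ, detectability = det, seed = seed + 1)
  occ <- drop_confined_species(dedup_within_radius(occ, 150), 256)
  lab <- expand_ranks(filter_min_count(neighbor_impute(occ, 256), 5),
                      synthetic_taxonomy(w))
  rs <- world_rasters(w)
  nm <- fit_climate_normalizer(rs$climate)
  out <- list(world = w, labels = lab, rasters = rs, normalizer = nm)
  .world_cache[[key]] <- out
  out
}

# Median per-species AUC of a model's strided prediction map against the
# world's true presence, restricted to map cells with world column > col_min
# and species with prevalence >= min_prev.
map_truth_aucs <- function(model, cw, window_px = 16, stride_px = 8,
                           col_min = 0) {
  w <- cw$world
  pm <- predict_map(model, cw$rasters$imagery, cw$rasters$climate,
                    cw$normalizer, window_px = window_px,
                    stride_px = stride_px, batch_size = 256)
  d <- dim(pm$probs)
  wc <- floor((pm$xmin + (seq_len(d[3]) - 1) * pm$res) / w$cell_m) + 1
  wr <- floor((w$ymax - (pm$ymax - (seq_len(d[2]) - 1) * pm$res)) / w$cell_m) + 1
  sel <- which(wc > col_min)
  vapply(seq_along(pm$species), function(s) {
    si <- match(pm$species[s], w$species)
    truth <- w$presence[si, , ][cbind(rep(wr, times = length(sel)),
                                      rep(wc[sel], each = length(wr)))]
    auc_roc(as.numeric(pm$probs[s, , sel]), truth)
  }, 0.0)
}

# Brute-force AUC oracle: explicit loop over all positive-negative pairs.
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}
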