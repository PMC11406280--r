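# Circular Gaussian smoothing of a matrix via the FFT. Periodic boundaries
# are fine for the simulator: fields only need to be smooth, not edge-exact.
gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  d <- dim(m)
  gr <- exp(-0.5 * (pmin(0:(d[1] - 1), d[1] - 0:(d[1] - 1)) / sigma)^2)
  gc <- exp(-0.5 * (pmin(0:(d[2] - 1), d[2] - 0:(d[2] - 1)) / sigma)^2)
  k <- outer(gr, gc)
  k <- k / sum(k)
  Re(stats::fft(stats::fft(m) * stats::fft(k), inverse = TRUE)) / length(m)
}

zscore <- function(m) (m - mean(m)) / stats::sd(as.numeric(m))

#' Generate a virtual ecosystem
#'
#' A seeded simulator producing everything the modeling pipeline consumes,
#' with a deliberate information split: climate-like smooth environmental
#' fields drive some species, a fine-scale categorical land-cover layer —
#' visible in the imagery texture but *not* in the environmental fields —
#' drives others. That separation makes the fused-versus-single-branch model
#' comparisons identifiable by construction.
#'
#' Species presence at cell `v` is `plogis(w_s . env(v) + a_s[landcover(v)]
#' + b_s) > u_s`, with `u_s` set to the quantile that realizes a target
#' prevalence drawn from `prevalence_range`. Imagery bands are per-class base
#' reflectances plus per-pixel texture noise. The sampling-effort field is a
#' smooth positive surface, optionally concentrated in one quadrant to mimic
#' the spatial bias of citizen-science observers.
#'
#' @param seed integer seed; the world is bit-for-bit reproducible from it.
#' @param R,C grid size in cells (one cell = one `cell_m` x `cell_m` plot).
#' @param S number of species.
#' @param B number of environmental (climate-like) bands.
#' @param m imagery pixels per cell side.
#' @param cell_m cell side length, meters.
#' @param n_landcover number of land-cover classes.
#' @param landcover_frac fraction of species whose niche loads on land cover.
#' @param env_sigma smoothing length of environmental fields, cells.
#' @param landcover_sigma smoothing length of the land-cover field, cells.
#' @param texture_sd per-pixel imagery texture noise SD (reflectance units).
#' @param prevalence_range admissible per-species prevalence interval.
#' @param effort_sigma smoothing length of the sampling-effort field, cells.
#' @param effort_bias multiplicative strength of smooth effort variation.
#' @param effort_quadrant optional quadrant index 1-4 receiving
#'   `effort_quadrant_weight` times the effort of the rest (heavy bias).
#' @param effort_quadrant_weight see `effort_quadrant`.
#' @param ecotone_col optional column index planting a sharp environmental
#'   discontinuity: all environmental bands are shifted by `ecotone_shift`
#'   for columns beyond it, producing an abrupt community transition.
#' @param ecotone_shift size of the planted environmental step.
#' @return an `sdm_world`: list with `env` (`B x R x C`), `landcover`
#'   (`R x C` integer), `imagery` (`4 x R*m x C*m`), `niche` (weights,
#'   affinities, intercepts, thresholds), `presence` (`S x R x C` binary),
#'   `effort` (`R x C`), `species` names, geometry fields and the seed.
#' @export
generate_world <- function(seed, R = 48, C = 48, S = 16, B = 19, m = 8,
                           cell_m = 256, n_landcover = 4,
                           landcover_frac = 0.5,
                           env_sigma = 8, landcover_sigma = 1.5,
                           texture_sd = 0.05,
                           prevalence_range = c(0.05, 0.4),
                           effort_sigma = 10, effort_bias = 1,
                           effort_quadrant = NULL,
                           effort_quadrant_weight = 20,
                           ecotone_col = NULL, ecotone_shift = 2) {
  stopifnot(R >= 1, C >= 1, S >= 1, B >= 1, m >= 1)
  set.seed(seed)
  env <- array(0, c(B, R, C))
  for (b in seq_len(B)) {
    fld <- zscore(gauss_smooth(matrix(stats::rnorm(R * C), R, C), env_sigma))
    if (!is.null(ecotone_col) && ecotone_col < C) {
      fld[, (ecotone_col + 1):C] <- fld[, (ecotone_col + 1):C] + ecotone_shift
    }
    env[b, , ] <- fld
  }
  lc_field <- gauss_smooth(matrix(stats::rnorm(R * C), R, C), landcover_sigma)
  lc_breaks <- stats::quantile(lc_field, probs = seq(0, 1, length.out = n_landcover + 1))
  landcover <- matrix(cut(lc_field, breaks = lc_breaks, labels = FALSE,
                          include.lowest = TRUE), R, C)
  # niches: every species loads on a few env bands; a landcover_frac subset
  # additionally (and dominantly) on land cover
  n_loads <- min(3L, B)
  w <- matrix(0, S, B)
  a <- matrix(0, S, n_landcover)
  uses_lc <- seq_len(S) <= round(landcover_frac * S)
  for (s in seq_len(S)) {
    bands <- sample.int(B, n_loads)
    w[s, bands] <- stats::rnorm(n_loads, sd = 1.5)
    if (uses_lc[s]) {
      w[s, ] <- w[s, ] * 0.3            # land cover dominates for these
      a[s, ] <- stats::rnorm(n_landcover, sd = 2.5)
    }
  }
  b0 <- numeric(S)
  env_mat <- matrix(env, B, R * C)      # B x cells
  lin <- w %*% env_mat + a[, as.integer(landcover), drop = FALSE] + b0
  pfield <- stats::plogis(lin)          # S x cells
  target_prev <- stats::runif(S, prevalence_range[1], prevalence_range[2])
  u <- numeric(S)
  presence <- matrix(0L, S, R * C)
  for (s in seq_len(S)) {
    u[s] <- stats::quantile(pfield[s, ], 1 - target_prev[s], names = FALSE)
    pres <- pfield[s, ] > u[s]
    if (!any(pres)) {  # constant field: fall back to top-k cells
      ord <- order(pfield[s, ], decreasing = TRUE)
      k <- max(1L, round(target_prev[s] * R * C))
      pres <- logical(R * C); pres[ord[seq_len(k)]] <- TRUE
    }
    presence[s, ] <- as.integer(pres)
  }
  if (any(rowSums(presence) == 0)) {
    stop("prevalence calibration failed for some species", call. = FALSE)
  }
  # imagery: per-class base reflectance in 4 bands + texture noise
  base <- matrix(stats::runif(n_landcover * 4, 0.15, 0.85), n_landcover, 4)
  HH <- R * m; WW <- C * m
  imagery <- array(0, c(4, HH, WW))
  cell_row <- rep(seq_len(R), each = m)
  cell_col <- rep(seq_len(C), each = m)
  lc_px <- landcover[cell_row, cell_col]  # HH x WW
  for (band in 1:4) {
    imagery[band, , ] <- pmin(1, pmax(0,
      matrix(base[lc_px, band], HH, WW) +
        matrix(stats::rnorm(HH * WW, sd = texture_sd), HH, WW)))
  }
  effort <- exp(effort_bias * zscore(gauss_smooth(matrix(stats::rnorm(R * C), R, C),
                                                  effort_sigma)))
  if (!is.null(effort_quadrant)) {
    qr <- if (effort_quadrant %in% c(1, 2)) seq_len(ceiling(R / 2)) else (ceiling(R / 2) + 1):R
    qc <- if (effort_quadrant %in% c(1, 3)) seq_len(ceiling(C / 2)) else (ceiling(C / 2) + 1):C
    wgt <- matrix(1, R, C); wgt[qr, qc] <- effort_quadrant_weight
    effort <- effort * wgt
  }
  structure(
    list(env = env, landcover = landcover, imagery = imagery,
         niche = list(w = w, a = a, b = b0, u = u, uses_landcover = uses_lc),
         presence = array(presence, c(S, R, C)),
         prob = array(pfield, c(S, R, C)),
         base_reflectance = base, texture_sd = texture_sd,
         effort = effort,
         species = sprintf("species_%03d", seq_len(S)),
         R = R, C = C, S = S, B = B, m = m, cell_m = cell_m,
         xmin = 0, ymax = R * cell_m, crs = "local",
         seed = seed),
    class = "sdm_world")
}

#' @export
print.sdm_world <- function(x, ...) {
  cat(sprintf("<sdm_world> %dx%d cells (%g m) | %d species | %d env bands | %d px/cell | seed %d\n",
              x$R, x$C, x$cell_m, x$S, x$B, x$m, x$seed))
  invisible(x)
}

#' World rasters
#'
#' Renders the world's imagery and environmental fields as georeferenced
#' rasters consumable by the sampling and mapping modules.
#'
#' @param world an `sdm_world`.
#' @return list with `imagery` (4-band, `cell_m/m` m/px) and `climate`
#'   (B-band, `cell_m` m/px) rasters.
#' @export
world_rasters <- function(world) {
  img <- new_raster(aperm(world$imagery, c(2, 3, 1)), world$xmin, world$ymax,
                    world$cell_m / world$m, world$crs,
                    band_names = c("red", "green", "blue", "nir"))
  clim <- new_raster(aperm(world$env, c(2, 3, 1)), world$xmin, world$ymax,
                     world$cell_m, world$crs,
                     band_names = sprintf("bio_%02d", seq_len(world$B)))
  list(imagery = img, climate = clim)
}

#' Simulate biased, incomplete occurrence records
#'
#' Anchor locations are drawn from the sampling-effort field (heavily visited
#' cells are sampled more), then each species truly present at the anchor's
#' cell is recorded independently with probability `detectability[s]` —
#' producing incomplete presence lists with systematic spatial bias, the data
#' pathology the sampling-aware loss targets.
#'
#' @param world an `sdm_world`.
#' @param n_target number of anchor visits to draw.
#' @param detectability per-species recording probability in (0, 1]
#'   (recycled).
#' @param seed integer seed.
#' @return occurrence data frame (`record_id, species, x, y, date, source`),
#'   one row per recorded species, with the world CRS attached.
#' @export
simulate_occurrences <- function(world, n_target, detectability = 0.5, seed = 1) {
  set.seed(seed)
  detectability <- rep_len(detectability, world$S)
  eff <- as.numeric(world$effort)
  if (n_target == 0 || all(eff <= 0)) {
    out <- data.frame(record_id = character(0), species = character(0),
                      x = numeric(0), y = numeric(0), date = character(0),
                      source = character(0))
    attr(out, "crs") <- world$crs
    return(out)
  }
  cells <- sample.int(world$R * world$C, n_target, replace = TRUE, prob = eff)
  rows <- ((cells - 1) %% world$R) + 1
  cols <- ((cells - 1) %/% world$R) + 1
  x <- world$xmin + (cols - 1 + stats::runif(n_target)) * world$cell_m
  y <- world$ymax - (rows - 1 + stats::runif(n_target)) * world$cell_m
  pres <- matrix(world$presence, world$S, world$R * world$C)
  recs <- vector("list", n_target)
  for (i in seq_len(n_target)) {
    present <- which(pres[, cells[i]] == 1)
    seen <- present[stats::runif(length(present)) < detectability[present]]
    if (length(seen) == 0) next
    recs[[i]] <- data.frame(anchor = i, species = world$species[seen],
                            x = x[i], y = y[i])
  }
  df <- do.call(rbind, recs)
  if (is.null(df)) {
    df <- data.frame(anchor = integer(0), species = character(0),
                     x = numeric(0), y = numeric(0))
  }
  out <- data.frame(record_id = sprintf("r%07d", seq_len(nrow(df))),
                    species = df$species, x = df$x, y = df$y,
                    date = NA_character_, source = "synthetic",
                    stringsAsFactors = FALSE)
  attr(out, "crs") <- world$crs
  out
}

#' Synthetic taxonomy
#'
#' Groups every 4 species into a genus and every 4 genera into a family, so
#' the three-rank label expansion and heads are exercised.
#'
#' @param species character vector of species names (or an `sdm_world`).
#' @return taxonomy data frame `species, genus, family`.
#' @export
synthetic_taxonomy <- function(species) {
  if (inherits(species, "sdm_world")) species <- species$species
  s <- seq_along(species)
  g <- (s - 1) %/% 4 + 1
  f <- (g - 1) %/% 4 + 1
  data.frame(species = species,
             genus = sprintf("genus_%03d", g),
             family = sprintf("family_%03d", f),
             stringsAsFactors = FALSE)
}

#' Ground-truth presence raster
#'
#' @param world an `sdm_world`.
#' @param species species index (1-based) or name.
#' @return single-band binary [sdm_raster][new_raster] at cell resolution.
#' @export
true_presence_map <- function(world, species) {
  if (is.character(species)) species <- match(species, world$species)
  if (is.na(species) || species < 1 || species > world$S) {
    stop("invalid species index", call. = FALSE)
  }
  new_raster(matrix(world$presence[species, , ], world$R, world$C),
             world$xmin, world$ymax, world$cell_m, world$crs,
             band_names = world$species[species])
}

#' Apply a land-cover disturbance to a world
#'
#' Cycles every land-cover class inside the given cell rectangle to the next
#' class (a stand-in for clear-cutting or fire), regenerates the imagery
#' texture deterministically with the same per-class reflectances, and
#' re-evaluates every species' niche — so both imagery and true communities
#' change inside the rectangle and nowhere else.
#'
#' @param world an `sdm_world`.
#' @param rows,cols integer ranges of disturbed cells.
#' @param seed seed for the regenerated imagery texture.
#' @return the disturbed `sdm_world`.
#' @export
disturb_world <- function(world, rows, cols, seed = world$seed + 1) {
  set.seed(seed)
  K <- nrow(world$base_reflectance)
  lc <- world$landcover
  lc[rows, cols] <- (lc[rows, cols] %% K) + 1L
  world$landcover <- lc
  m <- world$m
  cell_row <- rep(seq_len(world$R), each = m)
  cell_col <- rep(seq_len(world$C), each = m)
  lc_px <- lc[cell_row, cell_col]
  HH <- world$R * m; WW <- world$C * m
  for (band in 1:4) {
    world$imagery[band, , ] <- pmin(1, pmax(0,
      matrix(world$base_reflectance[lc_px, band], HH, WW) +
        matrix(stats::rnorm(HH * WW, sd = world$texture_sd), HH, WW)))
  }
  env_mat <- matrix(world$env, world$B, world$R * world$C)
  lin <- world$niche$w %*% env_mat +
    world$niche$a[, as.integer(lc), drop = FALSE] + world$niche$b
  pfield <- stats::plogis(lin)
  world$prob <- array(pfield, c(world$S, world$R, world$C))
  world$presence <- array((pfield > world$niche$u) * 1L,
                          c(world$S, world$R, world$C))
  world
}

#' True community probability stack
#'
#' The simulator's per-cell niche probabilities for every species, in the
#' `S x R x C` layout the community-change operators consume.
#'
#' @param world an `sdm_world`.
#' @return `S x R x C` array of probabilities.
#' @export
true_probability_map <- function(world) world$prob
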