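#' Model configuration
#'
#' Describes a fused (or single-branch) multilabel distribution model. The
#' reference full-scale settings follow the published layouts — a residual
#' 4-channel image encoder plus a climate perceptron with hidden layers
#' 1000, 1000, dropout 0.25, 2000, 2000 — but every width and depth is
#' configurable so the same architecture trains at desk scale (e.g. 32 px
#' patches, width-8 encoder) for testing.
#'
#' @param S,G,F counts of species, genus and family outputs.
#' @param climate_dim number of climate covariates (bands).
#' @param in_channels imagery channels (RGB + infrared = 4).
#' @param patch_px image patch side length in pixels.
#' @param mlp_hidden four hidden widths of the climate perceptron; dropout is
#'   applied after the second.
#' @param mlp_dropout dropout rate in `[0, 1)`.
#' @param encoder_width base channel width of the residual encoder.
#' @param encoder_depth number of residual stages; stage `i` has width
#'   `encoder_width * 2^(i-1)` and (for `i > 1`) halves resolution. The stem
#'   convolution also halves resolution, so inputs must be at least
#'   `2^encoder_depth` pixels on a side.
#' @param fusion_dim width of the fully connected fusion layer.
#' @param seed integer seed for weight initialization.
#' @return a `model_config` list.
#' @export
model_config <- function(S, G = S, F = S, climate_dim = 19, in_channels = 4,
                         patch_px = 256,
                         mlp_hidden = c(1000, 1000, 2000, 2000),
                         mlp_dropout = 0.25,
                         encoder_width = 64, encoder_depth = 3,
                         fusion_dim = 512, seed = 1) {
  stopifnot(S >= 1, G >= 1, F >= 1, climate_dim >= 1, in_channels >= 1,
            length(mlp_hidden) == 4, all(mlp_hidden >= 1),
            mlp_dropout >= 0, mlp_dropout < 1,
            encoder_width >= 1, encoder_depth >= 1, fusion_dim >= 1)
  structure(list(S = S, G = G, F = F, climate_dim = climate_dim,
                 in_channels = in_channels, patch_px = patch_px,
                 mlp_hidden = mlp_hidden, mlp_dropout = mlp_dropout,
                 encoder_width = encoder_width, encoder_depth = encoder_depth,
                 fusion_dim = fusion_dim, seed = seed),
            class = "model_config")
}

new_sdm_model <- function(arch, config, modules, feature_dims) {
  structure(list(arch = arch, config = config, modules = modules,
                 feature_dims = feature_dims, history = NULL, trained = FALSE,
                 index = NULL, normalizer = NULL),
            class = "sdm_model")
}

mlp_trunk <- function(cfg) {
  h <- cfg$mlp_hidden
  nn_seq(nn_linear(cfg$climate_dim, h[1]), nn_relu(),
         nn_linear(h[1], h[2]), nn_relu(),
         nn_dropout(cfg$mlp_dropout),
         nn_linear(h[2], h[3]), nn_relu(),
         nn_linear(h[3], h[4]), nn_relu())
}

encoder_trunk <- function(cfg) {
  w <- cfg$encoder_width
  mods <- list(nn_conv(cfg$in_channels, w, 3, stride = 2), nn_bn(w), nn_relu())
  c_in <- w
  for (i in seq_len(cfg$encoder_depth)) {
    c_out <- w * 2^(i - 1)
    mods <- c(mods, list(nn_resblock(c_in, c_out, stride = if (i > 1) 2 else 1)))
    c_in <- c_out
  }
  mods <- c(mods, list(nn_gap()))
  do.call(nn_seq, mods)
}

rank_heads <- function(d_in, cfg) {
  list(species = nn_linear(d_in, cfg$S, init_sd = 0.01),
       genus = nn_linear(d_in, cfg$G, init_sd = 0.01),
       family = nn_linear(d_in, cfg$F, init_sd = 0.01))
}

check_patch_size <- function(cfg) {
  min_px <- 2^cfg$encoder_depth
  if (cfg$patch_px < min_px) {
    stop(sprintf("patch_px = %d below the encoder's minimum downsampling footprint (%d px for depth %d)",
                 cfg$patch_px, min_px, cfg$encoder_depth), call. = FALSE)
  }
}

#' Build the climate perceptron model
#'
#' Feed-forward network `B -> h1 -> h2 -> dropout -> h3 -> h4` with rectifier
#' nonlinearities, followed by three parallel linear heads predicting species,
#' genus and family logits.
#'
#' @param config a [model_config()].
#' @return an `sdm_model` with `arch = "climate_mlp"`.
#' @export
build_climate_mlp <- function(config) {
  set.seed(config$seed)
  trunk <- mlp_trunk(config)
  heads <- rank_heads(config$mlp_hidden[4], config)
  new_sdm_model("climate_mlp", config,
                list(clim_trunk = trunk, heads = heads),
                list(clim = config$mlp_hidden[4]))
}

#' Build the residual image encoder model
#'
#' Residual convolutional encoder over 4-channel patches: a stride-2 stem
#' convolution, `encoder_depth` residual stages doubling in width, global
#' average pooling, then three parallel rank heads. Convolutions use
#' Kaiming-style initialization; the final batch-normalization scale of every
#' residual branch is zero-initialized, so each block acts as its shortcut at
#' initialization.
#'
#' @param config a [model_config()].
#' @return an `sdm_model` with `arch = "image_encoder"`.
#' @export
build_image_encoder <- function(config) {
  check_patch_size(config)
  set.seed(config$seed)
  trunk <- encoder_trunk(config)
  feat <- config$encoder_width * 2^(config$encoder_depth - 1)
  heads <- rank_heads(feat, config)
  new_sdm_model("image_encoder", config,
                list(img_trunk = trunk, heads = heads),
                list(img = feat))
}

#' Build the fused imagery + climate model
#'
#' The image encoder's pooled feature vector and the climate perceptron's
#' final hidden activations are concatenated, passed through one fully
#' connected fusion layer of width `fusion_dim` (with rectifier), then three
#' parallel rank heads. Both branches train jointly end-to-end.
#'
#' @param config a [model_config()].
#' @return an `sdm_model` with `arch = "fused"`.
#' @export
build_fused_model <- function(config) {
  check_patch_size(config)
  set.seed(config$seed)
  img_trunk <- encoder_trunk(config)
  clim_trunk <- mlp_trunk(config)
  feat_img <- config$encoder_width * 2^(config$encoder_depth - 1)
  feat_clim <- config$mlp_hidden[4]
  fusion <- nn_seq(nn_linear(feat_img + feat_clim, config$fusion_dim), nn_relu())
  heads <- rank_heads(config$fusion_dim, config)
  new_sdm_model("fused", config,
                list(img_trunk = img_trunk, clim_trunk = clim_trunk,
                     fusion = fusion, heads = heads),
                list(img = feat_img, clim = feat_clim))
}

# Full forward pass. img: (C,H,W,N) array or NULL; clim: (B x N) matrix or
# NULL. Returns list(model, logits = list(species, genus, family) as
# (units x N) matrices, caches) — caches are needed for the backward pass.
forward_model <- function(model, img = NULL, clim = NULL, training = FALSE) {
  m <- model$modules
  caches <- list()
  feats <- NULL
  if (model$arch %in% c("image_encoder", "fused")) {
    if (is.null(img)) stop("model requires imagery input", call. = FALSE)
    if (dim(img)[1] != model$config$in_channels) {
      stop(sprintf("expected %d image channels, got %d",
                   model$config$in_channels, dim(img)[1]), call. = FALSE)
    }
    f <- nn_forward(m$img_trunk, img, training)
    m$img_trunk <- f$mod; caches$img <- f$cache
    feats <- f$out
  }
  if (model$arch %in% c("climate_mlp", "fused")) {
    if (is.null(clim)) stop("model requires climate input", call. = FALSE)
    f <- nn_forward(m$clim_trunk, clim, training)
    m$clim_trunk <- f$mod; caches$clim <- f$cache
    feats <- if (is.null(feats)) f$out else rbind(feats, f$out)
  }
  if (model$arch == "fused") {
    f <- nn_forward(m$fusion, feats, training)
    m$fusion <- f$mod; caches$fusion <- f$cache
    feats <- f$out
  }
  logits <- list()
  for (rk in c("species", "genus", "family")) {
    f <- nn_forward(m$heads[[rk]], feats, training)
    m$heads[[rk]] <- f$mod
    caches[[paste0("head_", rk)]] <- f$cache
    logits[[rk]] <- f$out
  }
  model$modules <- m
  list(model = model, logits = logits, caches = caches)
}

# Backward pass given per-rank logit gradients ((units x N) matrices).
# Returns flat gradient list aligned with model_params(model).
backward_model <- function(model, caches, dlogits) {
  m <- model$modules
  grads <- list()
  dfeat <- NULL
  for (rk in c("species", "genus", "family")) {
    b <- nn_backward(m$heads[[rk]], caches[[paste0("head_", rk)]], dlogits[[rk]])
    grads <- c(grads, nn_flatten_grads(m$heads[[rk]], b$grads,
                                       paste0("heads.", rk, ".")))
    dfeat <- if (is.null(dfeat)) b$dx else dfeat + b$dx
  }
  if (model$arch == "fused") {
    b <- nn_backward(m$fusion, caches$fusion, dfeat)
    grads <- c(grads, nn_flatten_grads(m$fusion, b$grads, "fusion."))
    dfeat <- b$dx
    di <- model$feature_dims$img
    dimg_feat <- dfeat[seq_len(di), , drop = FALSE]
    dclim_feat <- dfeat[-seq_len(di), , drop = FALSE]
    bi <- nn_backward(m$img_trunk, caches$img, dimg_feat)
    grads <- c(grads, nn_flatten_grads(m$img_trunk, bi$grads, "img_trunk."))
    bc <- nn_backward(m$clim_trunk, caches$clim, dclim_feat)
    grads <- c(grads, nn_flatten_grads(m$clim_trunk, bc$grads, "clim_trunk."))
  } else if (model$arch == "image_encoder") {
    bi <- nn_backward(m$img_trunk, caches$img, dfeat)
    grads <- c(grads, nn_flatten_grads(m$img_trunk, bi$grads, "img_trunk."))
  } else {
    bc <- nn_backward(m$clim_trunk, caches$clim, dfeat)
    grads <- c(grads, nn_flatten_grads(m$clim_trunk, bc$grads, "clim_trunk."))
  }
  grads
}

model_params <- function(model) {
  out <- list()
  for (nm in names(model$modules)) {
    if (nm == "heads") {
      for (rk in names(model$modules$heads)) {
        out <- c(out, nn_params(model$modules$heads[[rk]],
                                paste0("heads.", rk, ".")))
      }
    } else {
      out <- c(out, nn_params(model$modules[[nm]], paste0(nm, ".")))
    }
  }
  out
}

model_set_params <- function(model, flat) {
  for (nm in names(model$modules)) {
    if (nm == "heads") {
      for (rk in names(model$modules$heads)) {
        model$modules$heads[[rk]] <- nn_set_params(model$modules$heads[[rk]],
                                                   flat, paste0("heads.", rk, "."))
      }
    } else {
      model$modules[[nm]] <- nn_set_params(model$modules[[nm]], flat,
                                           paste0(nm, "."))
    }
  }
  model
}

#' Predict species presence probabilities
#'
#' Species logits are mapped through the logistic function to independent
#' per-species presence probabilities (multilabel contract: a row does not sum
#' to one).
#'
#' @param model an `sdm_model`.
#' @param samples an `sdm_samples` object, or a list with elements `images`
#'   (`(C,H,W,N)` array) and/or `climate` (`B x N` matrix).
#' @return `N x S` matrix of probabilities in (0, 1).
#' @export
predict_probabilities <- function(model, samples) {
  f <- forward_model(model, img = samples$images, clim = samples$climate,
                     training = FALSE)
  p <- t(stats::plogis(f$logits$species))
  if (!is.null(model$index$species) && ncol(p) == length(model$index$species)) {
    colnames(p) <- model$index$species
  }
  p
}

#' @export
#' @param object,x an `sdm_model`.
#' @param ... unused.
#' @rdname predict_probabilities
#' @param newdata an `sdm_samples` object.
predict.sdm_model <- function(object, newdata, ...) {
  predict_probabilities(object, newdata)
}

#' @export
print.sdm_model <- function(x, ...) {
  np <- sum(vapply(model_params(x), length, 0L))
  cat(sprintf("<sdm_model:%s> S=%d G=%d F=%d | %s parameters | %s\n",
              x$arch, x$config$S, x$config$G, x$config$F,
              format(np, big.mark = ","),
              if (x$trained) sprintf("trained (epoch %d selected)",
                                     x$history$selected_epoch)
              else "initialized"))
  invisible(x)
}

#' @export
summary.sdm_model <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    h <- object$history$epochs
    cat(sprintf("  epochs: %d | final loss %.4f | best monitor AUC %.4f (epoch %d)\n",
                nrow(h), h$loss[nrow(h)],
                max(h$monitor_auc, na.rm = TRUE),
                object$history$selected_epoch))
  }
  invisible(object)
}

#' @export
plot.sdm_model <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history", call. = FALSE)
  h <- x$history$epochs
  graphics::par(mfrow = c(1, 2))
  graphics::plot(h$epoch, h$loss, type = "b", xlab = "epoch",
                 ylab = "training loss", main = "loss")
  graphics::plot(h$epoch, h$monitor_auc, type = "b", xlab = "epoch",
                 ylab = "mean per-species AUC", main = "monitoring AUC")
  graphics::abline(v = x$history$selected_epoch, lty = 2)
  invisible(x)
}

#' Model checkpoints
#'
#' A checkpoint is a JSON file carrying the architecture name, configuration,
#' all weights, the training history, and — when attached to the model — the
#' taxon index and climate normalizer, so a saved model is self-describing
#' and directly usable for mapping.
#'
#' @param model an `sdm_model`.
#' @param path JSON file path; `read_model()` reads it back.
#' @export
write_model <- function(model, path) {
  flat <- model_params(model)
  jsonlite::write_json(
    list(arch = model$arch, config = unclass(model$config),
         params = lapply(flat, function(p) list(dim = dim(p), values = as.numeric(p))),
         bn_state = collect_bn_state(model),
         history = if (is.null(model$history)) NULL else
           list(epochs = model$history$epochs,
                selected_epoch = model$history$selected_epoch),
         trained = model$trained,
         index = model$index,
         normalizer = if (is.null(model$normalizer)) NULL else unclass(model$normalizer)),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(model_config, j$config)
  model <- switch(j$arch,
    fused = build_fused_model(cfg),
    climate_mlp = build_climate_mlp(cfg),
    image_encoder = build_image_encoder(cfg),
    stop("unknown architecture: ", j$arch, call. = FALSE))
  flat <- lapply(j$params, function(p) {
    v <- p$values
    if (!is.null(p$dim) && length(p$dim)) dim(v) <- p$dim
    v
  })
  model <- model_set_params(model, flat)
  model <- restore_bn_state(model, j$bn_state)
  if (!is.null(j$history)) {
    model$history <- list(epochs = as.data.frame(j$history$epochs),
                          selected_epoch = j$history$selected_epoch)
  }
  model$trained <- isTRUE(j$trained)
  if (!is.null(j$index)) model$index <- j$index
  if (!is.null(j$normalizer)) {
    model$normalizer <- structure(j$normalizer, class = "sdm_normalizer")
  }
  model
}

# Batch-norm running statistics live in module $state, outside the flat
# parameter list; walk the tree to collect/restore them.
walk_bn <- function(mod, prefix, fn) {
  out <- list()
  if (identical(mod$type, "bn")) out[[prefix]] <- fn(mod)
  if (!is.null(mod$mods)) {
    keys <- names(mod$mods)
    if (is.null(keys)) keys <- as.character(seq_along(mod$mods))
    for (i in seq_along(mod$mods)) {
      if (is.null(mod$mods[[i]])) next
      key <- if (nzchar(keys[i])) keys[i] else as.character(i)
      out <- c(out, walk_bn(mod$mods[[i]], paste0(prefix, ".", key), fn))
    }
  }
  out
}

collect_bn_state <- function(model) {
  out <- list()
  for (nm in names(model$modules)) {
    if (nm == "heads") next
    out <- c(out, walk_bn(model$modules[[nm]], nm, function(m) m$state))
  }
  out
}

set_bn_state <- function(mod, prefix, states) {
  if (identical(mod$type, "bn") && !is.null(states[[prefix]])) {
    mod$state$mean <- as.numeric(states[[prefix]]$mean)
    mod$state$var <- as.numeric(states[[prefix]]$var)
  }
  if (!is.null(mod$mods)) {
    keys <- names(mod$mods)
    if (is.null(keys)) keys <- as.character(seq_along(mod$mods))
    for (i in seq_along(mod$mods)) {
      if (is.null(mod$mods[[i]])) next
      key <- if (nzchar(keys[i])) keys[i] else as.character(i)
      mod$mods[[i]] <- set_bn_state(mod$mods[[i]], paste0(prefix, ".", key), states)
    }
  }
  mod
}

restore_bn_state <- function(model, states) {
  if (is.null(states) || length(states) == 0) return(model)
  for (nm in names(model$modules)) {
    if (nm == "heads") next
    model$modules[[nm]] <- set_bn_state(model$modules[[nm]], nm, states)
  }
  model
}
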