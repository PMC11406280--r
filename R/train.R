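#' Estimate per-location survey completeness
#'
#' Citizen-science occurrence lists are incomplete, and more so in rarely
#' visited places. As a proxy for local survey completeness, the number of
#' distinct species observed within `radius_m` of each anchor (`n_i`) is
#' compared to a well-surveyed reference richness `n_ref`, the
#' `reference_quantile` of all `n_i`:
#' `c_i = min(1, n_i / n_ref)`.
#'
#' @param labels an `sdm_labels` object (anchors with species sets).
#' @param radius_m neighborhood radius, meters.
#' @param reference_quantile quantile of the richness distribution used as
#'   the "fully surveyed" reference.
#' @return named vector of completeness values in (0, 1], one per anchor id.
#' @export
estimate_location_completeness <- function(labels, radius_m = 256,
                                           reference_quantile = 0.95) {
  a <- labels$anchors
  n <- nrow(a)
  r2 <- radius_m^2
  n_i <- integer(n)
  block <- 512L
  for (start in seq(1, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(a$x[idx], a$x, `-`)^2 + outer(a$y[idx], a$y, `-`)^2
    for (k in seq_along(idx)) {
      nb <- which(d2[k, ] <= r2)
      n_i[idx[k]] <- length(unique(unlist(labels$species[nb], use.names = FALSE)))
    }
  }
  n_ref <- stats::quantile(n_i, reference_quantile, names = FALSE)
  if (n_ref == 0) stop("reference richness is zero", call. = FALSE)
  stats::setNames(pmin(1, n_i / n_ref), a$anchor_id)
}

#' Training configuration
#'
#' @param epochs number of optimization epochs.
#' @param learning_rate Adam step size.
#' @param batch_size mini-batch size.
#' @param loss_name `"sampling_aware_bce"`, `"bce"`, or `"ce"`.
#' @param rank_weights length-3 weights for species/genus/family loss terms.
#' @param seed integer seed controlling shuffling and dropout.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 13, learning_rate = 1e-3, batch_size = 64,
                         loss_name = "sampling_aware_bce",
                         rank_weights = c(1, 1, 1), seed = 1) {
  stopifnot(epochs >= 1, learning_rate >= 0, batch_size >= 1,
            length(rank_weights) == 3)
  structure(list(epochs = epochs, learning_rate = learning_rate,
                 batch_size = batch_size, loss_name = loss_name,
                 rank_weights = rank_weights, seed = seed),
            class = "train_config")
}

slice_inputs <- function(samples, idx) {
  list(images = if (is.null(samples$images)) NULL else
         samples$images[, , , idx, drop = FALSE],
       climate = if (is.null(samples$climate)) NULL else
         samples$climate[, idx, drop = FALSE])
}

# Mean per-species AUC_ROC of model predictions over the given sample indices
# (species with a single class among those rows are skipped).
monitor_auc <- function(model, samples, idx, batch_size = 256) {
  if (length(idx) == 0) return(NA_real_)
  probs <- NULL
  for (start in seq(1, length(idx), by = batch_size)) {
    sub <- idx[start:min(start + batch_size - 1L, length(idx))]
    p <- predict_probabilities(model, slice_inputs(samples, sub))
    probs <- rbind(probs, p)
  }
  tm <- targets_matrix(samples$targets$species[idx], ncol(probs))
  aucs <- vapply(seq_len(ncol(tm)), function(s) auc_roc(probs[, s], tm[, s]),
                 0.0)
  mean(aucs, na.rm = TRUE)
}

#' Train a distribution model
#'
#' Seeded mini-batch optimization with the Adam optimizer. After every epoch
#' the mean per-species AUC_ROC is computed on the monitoring (test) rows of
#' `split`; the returned model carries the weights of the best-monitored
#' epoch (early stopping by retrospective selection) and the full history.
#'
#' @param model an initialized `sdm_model`.
#' @param samples an `sdm_samples` object containing all anchors of `split`.
#' @param split an `sdm_split`; training rows come from `train_ids`, the
#'   monitoring rows from `test_ids`.
#' @param config a [train_config()].
#' @return the trained `sdm_model`; `model$history` holds `epochs` (data
#'   frame `epoch, loss, monitor_auc`) and `selected_epoch`.
#' @export
train_model <- function(model, samples, split, config = train_config()) {
  train_idx <- which(samples$anchor_id %in% split$train_ids)
  test_idx <- which(samples$anchor_id %in% split$test_ids)
  if (length(train_idx) == 0) stop("empty training set", call. = FALSE)
  set.seed(config$seed)
  params <- model_params(model)
  adam <- adam_init(names(params))
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     monitor_auc = numeric(0))
  best <- list(auc = -Inf, params = params, epoch = 0L)
  for (ep in seq_len(config$epochs)) {
    perm <- sample(train_idx)
    ep_loss <- 0
    n_batches <- 0L
    for (start in seq(1, length(perm), by = config$batch_size)) {
      bidx <- perm[start:min(start + config$batch_size - 1L, length(perm))]
      inp <- slice_inputs(samples, bidx)
      fw <- forward_model(model, img = inp$images, clim = inp$climate,
                          training = TRUE)
      model <- fw$model
      btargets <- lapply(samples$targets, function(t) t[bidx])
      res <- multirank_loss(fw$logits, btargets,
                            samples$completeness[bidx],
                            rank_weights = config$rank_weights,
                            loss_name = config$loss_name, grad = TRUE)
      if (!is.finite(res$loss)) {
        stop(sprintf("non-finite loss at epoch %d batch %d", ep, n_batches + 1),
             call. = FALSE)
      }
      ep_loss <- ep_loss + res$loss
      n_batches <- n_batches + 1L
      if (config$learning_rate > 0) {
        grads <- backward_model(model, fw$caches, res$dlogits)
        params <- model_params(model)
        upd <- adam_step(adam, params, grads, config$learning_rate)
        adam <- upd$state
        model <- model_set_params(model, upd$params)
      }
    }
    mauc <- monitor_auc(model, samples, test_idx)
    hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss / n_batches,
                                   monitor_auc = mauc))
    score <- if (is.na(mauc)) -Inf else mauc
    if (score > best$auc) {
      best <- list(auc = score, params = model_params(model), epoch = ep)
    }
  }
  if (best$epoch > 0) model <- model_set_params(model, best$params)
  sel <- if (best$epoch > 0) best$epoch else config$epochs
  model$history <- list(epochs = hist, selected_epoch = sel)
  model$trained <- TRUE
  model$index <- samples$index
  model
}

#' Learning-rate sweep grid
#'
#' Candidate Adam step sizes on a multiplicative half-decade grid spanning
#' `from` to `to` (each step multiplies by `10^0.5`).
#'
#' @param from,to grid endpoints.
#' @return numeric vector of learning rates.
#' @export
learning_rate_grid <- function(from = 5e-6, to = 1e-1) {
  out <- from * 10^(0.5 * (0:ceiling(2 * log10(to / from))))
  out[out <= to * (1 + 1e-12)]
}
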