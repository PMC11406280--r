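# log(sigmoid(z)) computed stably
log_sigmoid <- function(z) stats::plogis(z, log.p = TRUE)

#' Sampling-aware binary cross-entropy
#'
#' Binary cross-entropy for incompletely observed multilabel data. Within
#' each observation the present-species and absent-species log terms are
#' mean-balanced (so a handful of presences carries as much weight as
#' thousands of absences), and the absent term is scaled by the observation's
#' estimated survey completeness `c_i in (0, 1]`: where few of the truly
#' present species have been recorded, absences are weak evidence and are
#' downweighted accordingly.
#'
#' With `p = plogis(logits)`, `P_i` the positive and `A_i` the negative label
#' sets of row `i`:
#' \deqn{L = \frac{1}{N}\sum_i \left[ -\frac{1}{|P_i|}\sum_{s \in P_i} \log p_{is}
#'   - c_i \frac{1}{|A_i|}\sum_{s \in A_i} \log(1 - p_{is}) \right]}
#' A row without negatives contributes only its present term.
#'
#' @param logits `N x S` matrix of real-valued scores.
#' @param targets `N x S` binary matrix; every row needs at least one 1.
#' @param completeness length-N vector in (0, 1].
#' @param grad if `TRUE`, also return the analytic gradient w.r.t. `logits`.
#' @return the scalar loss, or (with `grad`) `list(loss, dlogits)`.
#' @export
sampling_aware_bce <- function(logits, targets, completeness = rep(1, nrow(logits)),
                               grad = FALSE) {
  stopifnot(all(dim(logits) == dim(targets)),
            length(completeness) == nrow(logits))
  n <- nrow(logits)
  np <- rowSums(targets)
  na_ <- rowSums(1 - targets)
  if (any(np == 0)) stop("every row must contain at least one positive", call. = FALSE)
  lp <- log_sigmoid(logits)    # log p
  ln <- log_sigmoid(-logits)   # log (1 - p)
  pos_term <- rowSums(lp * targets) / np
  neg_term <- ifelse(na_ > 0, rowSums(ln * (1 - targets)) / pmax(na_, 1), 0)
  loss <- mean(-pos_term - completeness * neg_term)
  if (!grad) return(loss)
  p <- stats::plogis(logits)
  dl <- matrix(0, n, ncol(logits))
  dl <- dl - targets * (1 - p) / (n * np)
  neg_scale <- ifelse(na_ > 0, completeness / (n * pmax(na_, 1)), 0)
  dl <- dl + (1 - targets) * p * neg_scale
  list(loss = loss, dlogits = dl)
}

#' Standard multilabel binary cross-entropy
#'
#' Element-wise binary cross-entropy averaged over all `N x S` entries.
#'
#' @inheritParams sampling_aware_bce
#' @return the scalar loss, or (with `grad`) `list(loss, dlogits)`.
#' @export
multilabel_bce <- function(logits, targets, grad = FALSE) {
  stopifnot(all(dim(logits) == dim(targets)))
  loss <- -mean(log_sigmoid(logits) * targets + log_sigmoid(-logits) * (1 - targets))
  if (!grad) return(loss)
  p <- stats::plogis(logits)
  list(loss = loss, dlogits = (p - targets) / length(targets))
}

#' Single-label softmax cross-entropy
#'
#' The single-label training style of earlier image-classification work: one
#' positive per observation (sampled uniformly from the label set upstream),
#' softmax over species, mean negative log-likelihood.
#'
#' @param logits `N x S` matrix.
#' @param target_idx length-N integer vector of 1-based positive indices.
#' @param grad if `TRUE`, also return the gradient.
#' @return scalar loss or `list(loss, dlogits)`.
#' @export
softmax_ce <- function(logits, target_idx, grad = FALSE) {
  n <- nrow(logits)
  zmax <- apply(logits, 1, max)
  lse <- zmax + log(rowSums(exp(logits - zmax)))
  picked <- logits[cbind(seq_len(n), target_idx)]
  loss <- mean(lse - picked)
  if (!grad) return(loss)
  sm <- exp(logits - lse)
  sm[cbind(seq_len(n), target_idx)] <- sm[cbind(seq_len(n), target_idx)] - 1
  list(loss = loss, dlogits = sm / n)
}

# Build a dense 0/1 target matrix (N x U) from a list of index vectors.
targets_matrix <- function(idx_list, n_units) {
  n <- length(idx_list)
  t_ <- matrix(0, n, n_units)
  for (i in seq_len(n)) t_[i, idx_list[[i]]] <- 1
  t_
}

#' Multi-rank training loss
#'
#' Weighted sum of the configured loss applied independently at the species,
#' genus and family ranks.
#'
#' @param logits list of `(units x N)` logit matrices named `species`,
#'   `genus`, `family` (the internal layout of [forward_model]).
#' @param targets list of index-vector lists per rank.
#' @param completeness length-N completeness weights.
#' @param rank_weights numeric length 3: species, genus, family weights.
#' @param loss_name `"sampling_aware_bce"`, `"bce"`, or `"ce"`.
#' @param grad if `TRUE`, also return per-rank logit gradients (transposed
#'   back to `(units x N)`).
#' @return scalar loss or `list(loss, dlogits)`.
#' @export
multirank_loss <- function(logits, targets, completeness,
                           rank_weights = c(1, 1, 1),
                           loss_name = "sampling_aware_bce", grad = FALSE) {
  ranks <- c("species", "genus", "family")
  total <- 0
  dl <- list()
  for (r in seq_along(ranks)) {
    rk <- ranks[r]
    w <- rank_weights[r]
    z <- t(logits[[rk]])  # N x U
    if (w == 0) {
      if (grad) dl[[rk]] <- matrix(0, ncol(z), nrow(z))
      next
    }
    tm <- targets_matrix(targets[[rk]], ncol(z))
    res <- switch(loss_name,
      sampling_aware_bce = sampling_aware_bce(z, tm, completeness, grad = grad),
      bce = multilabel_bce(z, tm, grad = grad),
      ce = {
        pick <- vapply(targets[[rk]], function(ix) {
          if (length(ix) == 1) ix else ix[sample.int(length(ix), 1)]
        }, 0L)
        softmax_ce(z, pick, grad = grad)
      },
      stop("unknown loss: ", loss_name, call. = FALSE))
    if (grad) {
      total <- total + w * res$loss
      dl[[rk]] <- w * t(res$dlogits)
    } else {
      total <- total + w * res
    }
  }
  if (grad) list(loss = total, dlogits = dl) else total
}
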