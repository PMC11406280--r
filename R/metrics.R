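#' Score matrix container
#'
#' Pairs an `N x S` matrix of presence scores with the binary targets the
#' metric suite evaluates against.
#'
#' @param scores `N x S` numeric matrix in `[0, 1]`.
#' @param targets `N x S` binary matrix; every row needs at least one 1.
#' @param species optional species names (length S).
#' @param anchor_ids optional observation ids (length N).
#' @return an object of class `sdm_scores`.
#' @export
score_matrix <- function(scores, targets, species = NULL, anchor_ids = NULL) {
  stopifnot(all(dim(scores) == dim(targets)),
            all(targets %in% c(0, 1)), all(rowSums(targets) >= 1))
  if (is.null(species)) species <- colnames(scores)
  if (is.null(species)) species <- sprintf("species_%04d", seq_len(ncol(scores)))
  structure(list(scores = scores, targets = targets, species = species,
                 anchor_ids = anchor_ids),
            class = "sdm_scores")
}

#' Area under the ROC curve
#'
#' Mann-Whitney construction: the probability that a uniformly drawn positive
#' outscores a uniformly drawn negative, with ties counting one half.
#' Undefined (returns `NA`) when either class is absent; such species are
#' excluded from aggregate medians.
#'
#' @param scores numeric score vector.
#' @param labels binary 0/1 vector of the same length.
#' @return AUC in `[0, 1]`, or `NA_real_`.
#' @export
auc_roc <- function(scores, labels) {
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

# Average precision with the step-wise construction; ranking ties broken by
# ascending index for reproducibility.
average_precision <- function(scores, labels) {
  npos <- sum(labels == 1)
  if (npos == 0) return(NA_real_)
  ord <- order(-scores, seq_along(scores))
  hits <- labels[ord] == 1
  prec_at <- cumsum(hits) / seq_along(hits)
  mean(prec_at[hits])
}

#' Area under the precision-recall curve
#'
#' Step-wise (average-precision) construction. Undefined without positives.
#'
#' @inheritParams auc_roc
#' @return AUC_PRC in `[0, 1]`, or `NA_real_`.
#' @export
auc_prc <- function(scores, labels) average_precision(scores, labels)

iqr_pair <- function(x) stats::quantile(x, c(0.25, 0.75), names = FALSE, na.rm = TRUE)

#' Thresholded binary classification metrics
#'
#' Presence is called where `score > threshold`. Per-species metrics are
#' computed down each species column, per-observation metrics across each
#' row. A species with zero predicted positives has undefined precision,
#' reported as 0 (the convention that keeps degenerate baselines comparable);
#' species with no true positives are excluded from per-species recall/F1
#' aggregation. Presence accuracy is the fraction of all true
#' (observation, present-species) pairs called present.
#'
#' @param sm an [score_matrix()].
#' @param threshold presence threshold in (0, 1).
#' @return list with `per_species` and `per_observation` data frames,
#'   `presence_accuracy`, and `aggregates` (medians and IQRs).
#' @export
threshold_metrics <- function(sm, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  pred <- sm$scores > threshold
  targ <- sm$targets == 1
  tp_s <- colSums(pred & targ)
  fp_s <- colSums(pred & !targ)
  fn_s <- colSums(!pred & targ)
  prec_s <- ifelse(tp_s + fp_s > 0, tp_s / (tp_s + fp_s), 0)
  rec_s <- ifelse(tp_s + fn_s > 0, tp_s / (tp_s + fn_s), NA_real_)
  f1_s <- ifelse(is.na(rec_s), NA_real_,
                 ifelse(prec_s + rec_s > 0, 2 * prec_s * rec_s / (prec_s + rec_s), 0))
  tp_o <- rowSums(pred & targ)
  fp_o <- rowSums(pred & !targ)
  fn_o <- rowSums(!pred & targ)
  prec_o <- ifelse(tp_o + fp_o > 0, tp_o / (tp_o + fp_o), 0)
  rec_o <- tp_o / (tp_o + fn_o)  # rows always have >= 1 positive
  f1_o <- ifelse(prec_o + rec_o > 0, 2 * prec_o * rec_o / (prec_o + rec_o), 0)
  list(
    per_species = data.frame(species = sm$species, support = tp_s + fn_s,
                             precision = prec_s, recall = rec_s, f1 = f1_s),
    per_observation = data.frame(precision = prec_o, recall = rec_o, f1 = f1_o),
    presence_accuracy = sum(tp_o) / sum(tp_o + fn_o),
    aggregates = list(
      precision_spp = stats::median(prec_s, na.rm = TRUE),
      precision_spp_iqr = iqr_pair(prec_s),
      recall_spp = stats::median(rec_s, na.rm = TRUE),
      recall_spp_iqr = iqr_pair(rec_s),
      f1_spp = stats::median(f1_s, na.rm = TRUE),
      f1_spp_iqr = iqr_pair(f1_s),
      recall_obs = stats::median(rec_o),
      recall_obs_iqr = iqr_pair(rec_o)))
}

#' Top-K ranking accuracy
#'
#' Per observation: the fraction of its true species ranked within the top K
#' scores of that row (ties broken by ascending species index); aggregated as
#' the mean over observations. Per species: over the observations containing
#' the species, the fraction where it ranks top-K; aggregated as the median
#' across species.
#'
#' @param sm an [score_matrix()].
#' @param K ranking cutoff, at most S.
#' @return list with `per_observation` (vector), `obs_mean`, `per_species`
#'   (vector), `spp_median`.
#' @export
topk_accuracy <- function(sm, K) {
  s_ <- ncol(sm$scores)
  stopifnot(K >= 1, K <= s_)
  n <- nrow(sm$scores)
  frac_obs <- numeric(n)
  in_top <- matrix(FALSE, n, s_)
  for (i in seq_len(n)) {
    ord <- order(-sm$scores[i, ], seq_len(s_))
    topk <- ord[seq_len(K)]
    in_top[i, topk] <- TRUE
    pos <- which(sm$targets[i, ] == 1)
    frac_obs[i] <- mean(pos %in% topk)
  }
  rate_spp <- vapply(seq_len(s_), function(s) {
    rows <- which(sm$targets[, s] == 1)
    if (length(rows) == 0) return(NA_real_)
    mean(in_top[rows, s])
  }, 0.0)
  list(per_observation = frac_obs, obs_mean = mean(frac_obs),
       per_species = rate_spp,
       spp_median = stats::median(rate_spp, na.rm = TRUE))
}

#' Mean average precision across species
#'
#' Average precision (step construction) of each species' score column over
#' observations, averaged over species with at least one positive.
#'
#' @param sm an [score_matrix()].
#' @return scalar mean average precision.
#' @export
mean_average_precision <- function(sm) {
  ap <- vapply(seq_len(ncol(sm$scores)), function(s)
    average_precision(sm$scores[, s], sm$targets[, s]), 0.0)
  mean(ap, na.rm = TRUE)
}

#' Full metric report for a score matrix
#'
#' Computes the binary (thresholded), discrimination (AUC) and ranking
#' (top-K, mean average precision) metric families, per species and per
#' observation, with median/IQR aggregates.
#'
#' @param sm an [score_matrix()].
#' @param threshold presence threshold.
#' @param topk integer vector of ranking cutoffs (values above S are skipped).
#' @return an `sdm_metric_report`: list with `per_species` data frame and
#'   `aggregates`.
#' @export
evaluate_scores <- function(sm, threshold = 0.5, topk = c(1, 5, 30, 100)) {
  topk <- topk[topk <= ncol(sm$scores)]
  th <- threshold_metrics(sm, threshold)
  auc_s <- vapply(seq_len(ncol(sm$scores)), function(s)
    auc_roc(sm$scores[, s], sm$targets[, s]), 0.0)
  prc_s <- vapply(seq_len(ncol(sm$scores)), function(s)
    auc_prc(sm$scores[, s], sm$targets[, s]), 0.0)
  per_species <- cbind(th$per_species,
                       auc_roc = auc_s, auc_prc = prc_s)
  agg <- th$aggregates
  agg$auc_roc_spp <- stats::median(auc_s, na.rm = TRUE)
  agg$auc_roc_spp_iqr <- iqr_pair(auc_s)
  agg$auc_prc_spp <- stats::median(prc_s, na.rm = TRUE)
  agg$auc_prc_spp_iqr <- iqr_pair(prc_s)
  agg$presence_accuracy <- th$presence_accuracy
  agg$mean_average_precision <- mean_average_precision(sm)
  for (K in topk) {
    tk <- topk_accuracy(sm, K)
    per_species[[sprintf("top%d", K)]] <- tk$per_species
    agg[[sprintf("top%d_obs", K)]] <- tk$obs_mean
    agg[[sprintf("top%d_spp", K)]] <- tk$spp_median
  }
  structure(list(per_species = per_species, aggregates = agg,
                 threshold = threshold, topk = topk),
            class = "sdm_metric_report")
}

#' @export
print.sdm_metric_report <- function(x, ...) {
  a <- x$aggregates
  cat(sprintf("<sdm_metric_report> %d species | threshold %.2f\n",
              nrow(x$per_species), x$threshold))
  cat(sprintf("  AUC_ROC_spp %.4f [%.2f, %.2f] | AUC_PRC_spp %.4f\n",
              a$auc_roc_spp, a$auc_roc_spp_iqr[1], a$auc_roc_spp_iqr[2],
              a$auc_prc_spp))
  cat(sprintf("  recall_obs %.4f | precision_spp %.4f | F1_spp %.4f | presence acc %.4f\n",
              a$recall_obs, a$precision_spp, a$f1_spp, a$presence_accuracy))
  for (K in x$topk) {
    cat(sprintf("  top-%d: obs %.4f | spp %.4f\n", K,
                a[[sprintf("top%d_obs", K)]], a[[sprintf("top%d_spp", K)]]))
  }
  invisible(x)
}

#' Random-score baseline
#'
#' Scores drawn i.i.d. from a standard normal distribution and mapped through
#' the logistic function, repeated `trials` times; the metric report's
#' aggregate scalars are averaged across trials.
#'
#' @param targets `N x S` binary target matrix.
#' @param trials number of random draws.
#' @param seed integer seed.
#' @param threshold,topk forwarded to [evaluate_scores()].
#' @return an `sdm_metric_report` whose aggregates are trial means (per-trial
#'   reports in `$trials`).
#' @export
random_baseline <- function(targets, trials = 10, seed = 1, threshold = 0.5,
                            topk = c(1, 5, 30, 100)) {
  stopifnot(trials >= 1)
  set.seed(seed)
  reports <- vector("list", trials)
  for (tr in seq_len(trials)) {
    sc <- matrix(stats::plogis(stats::rnorm(length(targets))),
                 nrow(targets), ncol(targets))
    reports[[tr]] <- evaluate_scores(score_matrix(sc, targets),
                                     threshold = threshold, topk = topk)
  }
  agg_names <- names(reports[[1]]$aggregates)
  avg <- stats::setNames(vector("list", length(agg_names)), agg_names)
  for (nm in agg_names) {
    vals <- vapply(reports, function(r) r$aggregates[[nm]][1], 0.0)
    if (grepl("_iqr$", nm)) {
      lo <- vapply(reports, function(r) r$aggregates[[nm]][1], 0.0)
      hi <- vapply(reports, function(r) r$aggregates[[nm]][2], 0.0)
      avg[[nm]] <- c(mean(lo), mean(hi))
    } else {
      avg[[nm]] <- mean(vals)
    }
  }
  structure(list(per_species = reports[[1]]$per_species, aggregates = avg,
                 threshold = threshold, topk = reports[[1]]$topk,
                 trials = reports),
            class = "sdm_metric_report")
}

#' Frequency baseline scores
#'
#' Each species receives a constant score: its relative frequency among
#' training label memberships, linearly rescaled so the rarest species maps
#' to 0.001 and the commonest to 1.0. The identical score row is repeated for
#' every evaluation observation.
#'
#' @param train_targets list of 1-based species index vectors (training label
#'   sets) or an `N x S` binary matrix.
#' @param n_obs number of evaluation observations.
#' @param n_species number of species (columns).
#' @return `n_obs x n_species` score matrix.
#' @export
frequency_baseline_scores <- function(train_targets, n_obs, n_species) {
  counts <- if (is.matrix(train_targets)) colSums(train_targets)
            else tabulate(unlist(train_targets), nbins = n_species)
  f <- counts / max(sum(counts), 1)
  rng <- range(f)
  sc <- if (rng[2] > rng[1]) 0.001 + (f - rng[1]) * (1 - 0.001) / (rng[2] - rng[1])
        else rep(1, n_species)
  matrix(sc, n_obs, n_species, byrow = TRUE)
}
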