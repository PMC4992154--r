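#' Partition clusters into K folds
#'
#' Randomly assigns each cluster (island) to exactly one of `K` folds with
#' fold sizes differing by at most one. A pure function of the cluster set,
#' `K` and `seed`; the caller's RNG state is untouched.
#'
#' @param cluster_ids character vector of cluster ids (duplicates allowed;
#'   the unique set is partitioned).
#' @param K number of folds.
#' @param seed RNG seed.
#' @return Named integer vector: fold number (1..K) per unique cluster id.
#' @export
kfold_partition <- function(cluster_ids, K, seed = 1L) {
  ids <- sort(unique(as.character(cluster_ids)))
  m <- length(ids)
  if (K < 2L || K > m) {
    stop("K must lie in [2, number of clusters]", call. = FALSE)
  }
  with_seed(seed, {
    perm <- sample(ids)
    sizes <- rep(m %/% K, K)
    extra <- m %% K
    if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    fold <- rep(seq_len(K), times = sizes)
    stats::setNames(fold[match(ids, perm)], ids)
  })
}

#' ROC curve and area under the curve
#'
#' AUC by the Mann-Whitney rank formulation with midrank tie correction:
#' the probability that a random positive outscores a random negative, with
#' ties counted 1/2. The curve is the step function of TPR/FPR over all
#' distinct score thresholds (classification rule: score >= threshold).
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 outcomes (both classes must be present).
#' @return List: `auc`, `curve` (data.frame threshold, tpr, fpr).
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop(structure(class = c("islex_degenerate_labels", "error", "condition"),
                   list(message = "both outcome classes must be present",
                        call = sys.call())))
  }
  r <- rank(scores)  # midranks handle ties
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  ord <- order(scores, decreasing = TRUE)
  s_sorted <- scores[ord]
  l_sorted <- labels[ord]
  cum_tp <- cumsum(l_sorted)
  cum_fp <- cumsum(1L - l_sorted)
  last <- cumsum(rle(s_sorted)$lengths)  # last index per distinct score
  curve <- data.frame(threshold = thr,
                      tpr = cum_tp[last] / n1,
                      fpr = cum_fp[last] / n0)
  rownames(curve) <- NULL
  list(auc = auc, curve = curve)
}

#' The four prediction-error statistics
#'
#' For errors `e = observed - predicted`: mean prediction error, mean
#' absolute prediction error, standard deviation of the prediction error
#' (n-1 denominator), and mean square error.
#'
#' @param observed,predicted equal-length numeric vectors.
#' @return Named numeric vector `(mean_error, mean_abs_error, sd_error,
#'   mse)`.
#' @export
error_stats <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length", call. = FALSE)
  }
  e <- observed - predicted
  c(mean_error = mean(e), mean_abs_error = mean(abs(e)),
    sd_error = stats::sd(e), mse = mean(e^2))
}

#' Repeated cluster-level K-fold cross-validation
#'
#' For each repeat, islands are partitioned into `K` folds; for each fold,
#' the model is refit on the training islands and the held-out rows are
#' scored, yielding one validation run per repeat-fold (so `repeats * K`
#' runs). Each run records the four error statistics and the AUC. A run
#' whose test fold contains a single outcome class has no AUC; it is
#' recorded as missing and excluded from AUC aggregates, with the count
#' reported. Clusters never straddle training and test sets.
#'
#' @param ds an [islex_dataset()].
#' @param spec an [model_spec()].
#' @param K folds (default 10).
#' @param repeats repeats of the whole partition (default 10).
#' @param seed base RNG seed; repeat `r` uses `seed + r - 1`.
#' @param use_historical_presence design flag, see [build_design()].
#' @return List of class `islex_cv`: `runs` (data.frame repeat_id, fold_id,
#'   auc, mean_error, mean_abs_error, sd_error, mse, n_test_rows, seed),
#'   `aggregates` (mean/sd/se of AUC over defined runs; means of error
#'   statistics), `n_skipped_auc`.
#' @export
cross_validate <- function(ds, spec, K = 10L, repeats = 10L, seed = 1L,
                           use_historical_presence = TRUE) {
  dm <- build_design(ds, spec, use_historical_presence)
  runs <- vector("list", repeats * K)
  k_run <- 0L
  for (r in seq_len(repeats)) {
    fold_of <- kfold_partition(dm$cluster, K, seed = seed + r - 1L)
    row_fold <- fold_of[dm$cluster]
    for (k in seq_len(K)) {
      test_idx <- which(row_fold == k)
      train_idx <- which(row_fold != k)
      stopifnot(length(intersect(unique(dm$cluster[test_idx]),
                                 unique(dm$cluster[train_idx]))) == 0L)
      fit <- tryCatch(fit_gee(design_subset(dm, train_idx)),
                      error = function(e) NULL)
      k_run <- k_run + 1L
      if (is.null(fit)) {
        runs[[k_run]] <- data.frame(repeat_id = r, fold_id = k,
                                    auc = NA_real_, mean_error = NA_real_,
                                    mean_abs_error = NA_real_,
                                    sd_error = NA_real_, mse = NA_real_,
                                    n_test_rows = length(test_idx),
                                    seed = seed + r - 1L)
        next
      }
      test_dm <- design_subset(dm, test_idx)
      pred <- predict_probability(fit, test_dm)
      es <- error_stats(as.numeric(test_dm$y), pred)
      auc <- tryCatch(roc_auc(pred, test_dm$y)$auc,
                      islex_degenerate_labels = function(e) NA_real_)
      runs[[k_run]] <- data.frame(repeat_id = r, fold_id = k, auc = auc,
                                  mean_error = es[["mean_error"]],
                                  mean_abs_error = es[["mean_abs_error"]],
                                  sd_error = es[["sd_error"]],
                                  mse = es[["mse"]],
                                  n_test_rows = length(test_idx),
                                  seed = seed + r - 1L)
    }
  }
  runs <- do.call(rbind, runs)
  auc_ok <- !is.na(runs$auc)
  aggregates <- list(
    auc_mean = mean(runs$auc[auc_ok]),
    auc_sd = stats::sd(runs$auc[auc_ok]),
    auc_se = stats::sd(runs$auc[auc_ok]) / sqrt(sum(auc_ok)),
    n_runs = nrow(runs), n_runs_auc = sum(auc_ok),
    mean_error = mean(runs$mean_error, na.rm = TRUE),
    mean_abs_error = mean(runs$mean_abs_error, na.rm = TRUE),
    sd_error = mean(runs$sd_error, na.rm = TRUE),
    mse = mean(runs$mse, na.rm = TRUE)
  )
  structure(list(runs = runs, aggregates = aggregates,
                 n_skipped_auc = sum(!auc_ok)),
            class = "islex_cv")
}

#' @export
print.islex_cv <- function(x, ...) {
  a <- x$aggregates
  cat(sprintf("cluster K-fold CV: %d runs (%d with AUC)\n",
              a$n_runs, a$n_runs_auc))
  cat(sprintf("AUC mean %.3f (sd %.3f, se %.4f); MSE %.4f; MAE %.4f\n",
              a$auc_mean, a$auc_sd, a$auc_se, a$mse, a$mean_abs_error))
  invisible(x)
}

#' Leave-one-island-out influence diagnostics
#'
#' Exact deletion diagnostics at the cluster level: the model is refit with
#' each island removed (initialised at the full-data coefficients), and the
#' coefficient displacement `dbeta = beta_full - beta_(-i)` is summarised by
#' a Cook-type aggregate `dbeta' robust_cov^{-1} dbeta`. Observation-level
#' deltas are then computed by exact single-row deletions within the most
#' influential cluster(s). Deletions that leave a rank-deficient or
#' non-convergent fit are flagged, not dropped silently.
#'
#' @param ds an [islex_dataset()].
#' @param spec an [model_spec()].
#' @param n_detail number of top-ranked clusters whose rows get
#'   observation-level deltas (default 1).
#' @param use_historical_presence design flag.
#' @return List of class `islex_influence`: `clusters` (data.frame ranked by
#'   cook), `observations` (row-deletion table within top clusters),
#'   `full_fit`.
#' @export
cluster_influence <- function(ds, spec, n_detail = 1L,
                              use_historical_presence = TRUE) {
  dm <- build_design(ds, spec, use_historical_presence)
  full <- fit_gee(dm)
  if (!full$converged) stop("full-data fit did not converge", call. = FALSE)
  Vinv <- solve(full$robust_cov)
  ids <- unique(dm$cluster)
  res <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    idx <- which(dm$cluster != ids[i])
    fit_i <- tryCatch(fit_gee(design_subset(dm, idx),
                              beta_init = full$beta),
                      error = function(e) NULL)
    ok <- !is.null(fit_i) && fit_i$converged
    db <- if (ok) full$beta - fit_i$beta else rep(NA_real_, length(full$beta))
    res[[i]] <- data.frame(cluster = ids[i],
                           cook = if (ok) drop(t(db) %*% Vinv %*% db)
                                  else NA_real_,
                           max_abs_dbeta = if (ok) max(abs(db)) else NA_real_,
                           n_rows = sum(dm$cluster == ids[i]),
                           ok = ok, stringsAsFactors = FALSE)
  }
  clusters <- do.call(rbind, res)
  clusters <- clusters[order(-ifelse(clusters$ok, clusters$cook, -Inf)), ,
                       drop = FALSE]
  rownames(clusters) <- NULL
  top <- utils::head(clusters$cluster[clusters$ok], n_detail)
  obs <- NULL
  if (length(top) > 0L) {
    rows <- which(dm$cluster %in% top)
    ores <- vector("list", length(rows))
    for (j in seq_along(rows)) {
      idx <- setdiff(seq_len(nrow(dm$X)), rows[j])
      fit_j <- tryCatch(fit_gee(design_subset(dm, idx),
                                beta_init = full$beta),
                        error = function(e) NULL)
      ok <- !is.null(fit_j) && fit_j$converged
      db <- if (ok) full$beta - fit_j$beta else rep(NA_real_,
                                                    length(full$beta))
      ores[[j]] <- data.frame(cluster = dm$cluster[rows[j]],
                              species_id = dm$keys$species_id[rows[j]],
                              cook = if (ok) drop(t(db) %*% Vinv %*% db)
                                     else NA_real_,
                              ok = ok, stringsAsFactors = FALSE)
    }
    obs <- do.call(rbind, ores)
    obs <- obs[order(-ifelse(obs$ok, obs$cook, -Inf)), , drop = FALSE]
    rownames(obs) <- NULL
  }
  structure(list(clusters = clusters, observations = obs, full_fit = full),
            class = "islex_influence")
}
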