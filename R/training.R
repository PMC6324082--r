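# Model construction: gradient-boosted decision stumps (depth-1 trees) with
# logistic loss, signed leaf-score feature importances, importance-threshold
# feature selection, repeated stratified k-fold cross-validation, and the two
# classification-threshold calibration rules.

#' Training configuration
#'
#' @param folds Number of cross-validation folds.
#' @param repeats Number of repeated CV runs.
#' @param seed Integer seed controlling fold assignment and any stochastic
#'   training step.
#' @param learning_rate Shrinkage applied to every leaf value.
#' @param nrounds Number of boosting rounds.
#' @param lambda L2 regularization on leaf values.
#' @param importance_cutoff Feature-selection cutoff on absolute importance.
#' @return A `training_config` list.
#' @export
training_config <- function(folds = 5L, repeats = 100L, seed = 0L,
                            learning_rate = 0.3, nrounds = 100L,
                            lambda = 1, importance_cutoff = 0.02) {
  stopifnot(folds >= 2L, repeats >= 1L, importance_cutoff > 0,
            learning_rate > 0, nrounds >= 1L, lambda >= 0)
  structure(list(folds = as.integer(folds), repeats = as.integer(repeats),
                 seed = as.integer(seed), learning_rate = learning_rate,
                 nrounds = as.integer(nrounds), lambda = lambda,
                 importance_cutoff = importance_cutoff),
            class = "training_config")
}

.as_cohort_matrix <- function(cohort) {
  if (is.data.frame(cohort)) {
    stopifnot("label" %in% names(cohort))
    y <- as.integer(cohort$label)
    drop <- names(cohort) %in% c("label", "protein_id")
    X <- as.matrix(cohort[, !drop, drop = FALSE])
    storage.mode(X) <- "double"
    list(X = X, y = y)
  } else {
    stopifnot(is.list(cohort), !is.null(cohort$X), !is.null(cohort$y))
    list(X = as.matrix(cohort$X), y = as.integer(cohort$y))
  }
}

#' Fit a boosted ensemble of decision stumps
#'
#' Gradient boosting with logistic loss where every tree is a single split
#' (depth 1). Each round scans all features and all split points for the
#' split maximizing the regularized gain
#' `G_L^2/(H_L+lambda) + G_R^2/(H_R+lambda) - G^2/(H+lambda)`
#' (G, H: sums of first/second-order loss gradients); ties go to the
#' lowest-index feature and smallest split. Rounds whose best gain is not
#' positive contribute an intercept-only update. Leaf values are shrunk by
#' the learning rate. Training is deterministic: identical data and
#' configuration give identical ensembles.
#'
#' Two per-feature importances are exposed. `importance` is the summed signed
#' leaf-score contribution of the feature across its trees, oriented so that
#' a positive value means high feature values (or indicator true) raise the
#' predicted score — the convention of the weights in [tes_weights()].
#' `gain_importance` is the feature's share of the total split gain
#' (non-negative, summing to 1), the statistic boosting libraries report as
#' feature importance and the one [select_features()] filters on.
#'
#' @param cohort A data.frame with binary `label` column plus numeric feature
#'   columns (an optional `protein_id` column is ignored), or a list
#'   `list(X = matrix, y = 0/1 vector)`.
#' @param config A [training_config()].
#' @return A `stump_ensemble` with elements `trees` (data.frame: `feature`,
#'   `split`, `left`, `right` — `left` applies when value < split),
#'   `base` (accumulated intercept), `importance` (named numeric),
#'   `feature_names`, `config`.
#' @export
fit_stump_ensemble <- function(cohort, config = training_config()) {
  dat <- .as_cohort_matrix(cohort)
  X <- dat$X; y <- dat$y
  if (length(unique(y)) < 2L) {
    stop("cohort must contain both classes", call. = FALSE)
  }
  n <- nrow(X); p <- ncol(X)
  eta <- config$learning_rate; lam <- config$lambda

  # per-feature presort; NA values are imputed to +Inf so they fall on the
  # "not below threshold" side, matching the scoring module's convention
  Ximp <- X
  Ximp[is.na(Ximp)] <- Inf
  ords <- lapply(seq_len(p), function(j) order(Ximp[, j]))
  # candidate split positions: last index of each tied group except the final
  cuts <- lapply(seq_len(p), function(j) {
    v <- Ximp[ords[[j]], j]
    which(v[-n] != v[-1])
  })

  f <- rep(0, n)
  trees <- vector("list", config$nrounds)
  gain_acc <- numeric(p)
  base <- 0
  for (r in seq_len(config$nrounds)) {
    prob <- 1 / (1 + exp(-f))
    g <- prob - y
    h <- prob * (1 - prob)
    G <- sum(g); H <- sum(h)
    best <- list(gain = 0, feature = NA_integer_, split = NA_real_)
    for (j in seq_len(p)) {
      ks <- cuts[[j]]
      if (!length(ks)) next
      gs <- cumsum(g[ords[[j]]])[ks]
      hs <- cumsum(h[ords[[j]]])[ks]
      gain <- gs^2 / (hs + lam) + (G - gs)^2 / (H - hs + lam) -
        G^2 / (H + lam)
      kbest <- which.max(gain)
      if (gain[kbest] > best$gain + 1e-12) {
        v <- Ximp[ords[[j]], j]
        best <- list(gain = gain[kbest], feature = j,
                     split = (v[ks[kbest]] + v[ks[kbest] + 1L]) / 2,
                     GL = gs[kbest], HL = hs[kbest])
      }
    }
    if (is.na(best$feature)) {
      w <- -eta * G / (H + lam)        # intercept-only round
      f <- f + w
      base <- base + w
    } else {
      wl <- -eta * best$GL / (best$HL + lam)
      wr <- -eta * (G - best$GL) / (H - best$HL + lam)
      below <- Ximp[, best$feature] < best$split
      f <- f + ifelse(below, wl, wr)
      gain_acc[best$feature] <- gain_acc[best$feature] + best$gain
      trees[[r]] <- data.frame(feature = best$feature, split = best$split,
                               left = wl, right = wr)
    }
  }
  trees <- do.call(rbind, trees[!vapply(trees, is.null, TRUE)])
  if (is.null(trees)) {
    trees <- data.frame(feature = integer(0), split = numeric(0),
                        left = numeric(0), right = numeric(0))
  }
  fn <- colnames(X)
  if (is.null(fn)) fn <- paste0("f", seq_len(p))
  imp <- stats::setNames(numeric(p), fn)
  if (nrow(trees)) {
    contrib <- tapply(trees$right - trees$left, trees$feature, sum)
    imp[as.integer(names(contrib))] <- as.numeric(contrib)
  }
  gain_imp <- stats::setNames(
    if (sum(gain_acc) > 0) gain_acc / sum(gain_acc) else gain_acc, fn)
  structure(list(trees = trees, base = base, importance = imp,
                 gain_importance = gain_imp,
                 feature_names = fn, config = config),
            class = "stump_ensemble")
}

#' @export
print.stump_ensemble <- function(x, ...) {
  cat(sprintf("Boosted stump ensemble: %d split trees over %d features\n",
              nrow(x$trees), length(x$feature_names)))
  top <- sort(abs(x$importance), decreasing = TRUE)
  top <- top[top > 0][seq_len(min(5, sum(top > 0)))]
  if (length(top)) {
    cat("Top |importance|:",
        paste(sprintf("%s=%.3f", names(top), x$importance[names(top)]),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Predict margins from a stump ensemble
#'
#' @param object A `stump_ensemble`.
#' @param newdata Matrix or data.frame with the training feature columns.
#' @param type `"margin"` (log-odds, default) or `"response"` (probability).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.stump_ensemble <- function(object, newdata, type = c("margin", "response"),
                                   ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata)) {
    newdata <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  }
  storage.mode(newdata) <- "double"
  newdata[is.na(newdata)] <- Inf
  f <- rep(object$base, nrow(newdata))
  tr <- object$trees
  for (i in seq_len(nrow(tr))) {
    below <- newdata[, tr$feature[i]] < tr$split[i]
    f <- f + ifelse(below, tr$left[i], tr$right[i])
  }
  if (type == "response") 1 / (1 + exp(-f)) else f
}

#' Importance-threshold feature selection
#'
#' Keeps the features whose absolute importance is strictly greater than the
#' cutoff (a value exactly at the cutoff is excluded). Given a fitted
#' ensemble, the filter runs on its normalized gain importance — the
#' statistic boosting libraries report as feature importance, on which a
#' cutoff like 0.02 is meaningful regardless of cohort size; a named numeric
#' vector is filtered as supplied.
#'
#' @param ensemble A `stump_ensemble`, or a named numeric importance vector.
#' @param cutoff Strict lower bound on `|importance|`.
#' @return Character vector of selected feature names.
#' @export
select_features <- function(ensemble, cutoff = 0.02) {
  stopifnot(cutoff > 0)
  imp <- if (inherits(ensemble, "stump_ensemble")) {
    ensemble$gain_importance
  } else {
    ensemble
  }
  names(imp)[abs(imp) > cutoff]
}

#' Expand a fitted ensemble into an indicator weight table
#'
#' Aggregates the ensemble's stumps into `*_below(threshold)` /
#' `go_term`-style indicator features with signed weights, the same shape as
#' [tes_weights()]: for each distinct (feature, split) the weight of the
#' indicator "value < split" is the summed `left - right` leaf difference,
#' while binary 0/1 feature columns named like GO ids become `go_term`
#' features weighted by `right - left` (indicator true raises the score).
#'
#' @param ensemble A `stump_ensemble`.
#' @param go_pattern Regular expression identifying GO-indicator columns.
#' @return A weight-table data.frame compatible with [score_cohort()].
#' @export
as_weight_table <- function(ensemble, go_pattern = "^GO:") {
  tr <- ensemble$trees
  if (!nrow(tr)) {
    return(data.frame(feature_id = character(0), kind = character(0),
                      term = character(0), threshold = numeric(0),
                      weight = numeric(0), description = character(0),
                      stringsAsFactors = FALSE))
  }
  fname <- ensemble$feature_names[tr$feature]
  key <- paste(fname, tr$split, sep = "@")
  agg <- tapply(seq_len(nrow(tr)), key, function(idx) {
    f <- fname[idx[1]]
    if (grepl(go_pattern, f)) {
      data.frame(feature_id = f, kind = "go_term", term = f,
                 threshold = NA_real_,
                 weight = sum(tr$right[idx] - tr$left[idx]),
                 description = f, stringsAsFactors = FALSE)
    } else {
      thr <- tr$split[idx[1]]
      data.frame(feature_id = sprintf("%s_below_%g", f, thr),
                 kind = paste0(f, "_below"), term = NA_character_,
                 threshold = thr,
                 weight = sum(tr$left[idx] - tr$right[idx]),
                 description = sprintf("%s lower than %g", f, thr),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(-out$weight), , drop = FALSE]
}

# Mann-Whitney AUC of scores for binary labels.
.auc <- function(scores, labels) {
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# Stratified fold assignment: within each class, shuffle and deal round-robin.
.stratified_folds <- function(y, k, rng) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[.lcg_shuffle(rng, length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Repeated stratified k-fold cross-validation
#'
#' Re-randomizes a stratified k-fold split on every repeat (from the run
#' seed), fits a stump ensemble on each training fold and scores the held-out
#' fold. Per-run AUC is computed on the pooled held-out predictions of that
#' run (set `pool = FALSE` to average per-fold AUCs instead). Per-run
#' precision-recall and Matthews-correlation curves over all observed score
#' thresholds are returned when `curves = TRUE`.
#'
#' @param cohort As in [fit_stump_ensemble()].
#' @param config A [training_config()]; `folds`, `repeats`, `seed` drive CV.
#' @param pool Pool held-out predictions per run (default) or average
#'   per-fold AUCs.
#' @param curves Also compute per-run PR/MCC curves.
#' @return A `cv_report` list: `auc` (length `repeats`), `summary`
#'   (mean/min/max/sd), `curves` (list of per-run data.frames with columns
#'   `threshold`, `recall`, `precision`, `fallout`, `f1`, `mcc`), `config`.
#' @export
cross_validate <- function(cohort, config = training_config(),
                           pool = TRUE, curves = FALSE) {
  dat <- .as_cohort_matrix(cohort)
  X <- dat$X; y <- dat$y
  if (nrow(X) < config$folds) stop("cohort smaller than fold count", call. = FALSE)
  if (min(table(y)) < config$folds) {
    stop("too few members of one class to stratify into ", config$folds,
         " folds", call. = FALSE)
  }
  rng <- .lcg_new(config$seed)
  aucs <- numeric(config$repeats)
  curve_list <- if (curves) vector("list", config$repeats) else NULL
  cn <- colnames(X)
  for (r in seq_len(config$repeats)) {
    fold <- .stratified_folds(y, config$folds, rng)
    pred <- numeric(length(y))
    fold_auc <- numeric(config$folds)
    for (k in seq_len(config$folds)) {
      tr_idx <- fold != k
      Xtr <- X[tr_idx, , drop = FALSE]; colnames(Xtr) <- cn
      ens <- fit_stump_ensemble(list(X = Xtr, y = y[tr_idx]), config)
      pred[!tr_idx] <- predict(ens, X[!tr_idx, , drop = FALSE])
      fold_auc[k] <- .auc(pred[!tr_idx], y[!tr_idx])
    }
    aucs[r] <- if (pool) .auc(pred, y) else mean(fold_auc)
    if (curves) curve_list[[r]] <- classification_curves(pred, y)
  }
  structure(list(auc = aucs,
                 summary = c(mean = mean(aucs), min = min(aucs),
                             max = max(aucs), sd = stats::sd(aucs)),
                 curves = curve_list, config = config),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("CV: %d runs of %d-fold; AUC mean %.4f (min %.4f, max %.4f, sd %.4f)\n",
              length(x$auc), x$config$folds, s["mean"], s["min"], s["max"],
              s["sd"]))
  invisible(x)
}

#' Classification performance curves
#'
#' Recall, precision, fallout (false-positive rate), F1 and Matthews
#' correlation of the rule "predict positive iff score >= t" at every
#' observed score threshold.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels.
#' @return data.frame with columns `threshold`, `recall`, `precision`,
#'   `fallout`, `f1`, `mcc`, one row per distinct score, decreasing
#'   threshold.
#' @export
classification_curves <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  thr <- sort(unique(scores), decreasing = TRUE)
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  ctp <- cumsum(l); cfp <- cumsum(1L - l)
  last <- findInterval(-thr, -s)       # index of last score >= thr
  tp <- ctp[last]; fp <- cfp[last]
  fn <- npos - tp; tn <- nneg - fp
  recall <- tp / npos
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  fallout <- fp / nneg
  f1 <- ifelse(!is.na(precision) & (precision + recall) > 0,
               2 * precision * recall / (precision + recall), 0)
  denom <- sqrt((tp + fp) * (tp + fn)) * sqrt((tn + fp) * (tn + fn))
  mcc <- ifelse(denom > 0, (tp * tn - fp * fn) / denom, 0)
  data.frame(threshold = thr, recall = recall, precision = precision,
             fallout = fallout, f1 = f1, mcc = mcc)
}

#' F1-maximizing threshold scan
#'
#' Scans every distinct observed score as a candidate threshold for the rule
#' "predict positive iff score >= t" and returns the threshold maximizing the
#' F1 score (harmonic mean of precision and recall), together with the full
#' recall/precision/fallout/F1 curves. Ties are broken toward the smallest
#' optimal threshold. Because candidates are the observed scores, the result
#' depends only on score ranks: any strictly increasing transform of the
#' scores yields the transformed optimum.
#'
#' @param scores Numeric scores (e.g. normalized TES values).
#' @param labels 0/1 labels; both classes must be present.
#' @return List with `threshold`, `f1`, `recall`, `precision`, `fallout`,
#'   and `curves` (the [classification_curves()] data.frame).
#' @export
f1_threshold_scan <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("threshold scan requires both classes", call. = FALSE)
  }
  cur <- classification_curves(scores, labels)
  best_f1 <- max(cur$f1)
  i <- which(cur$f1 >= best_f1 - 1e-12)
  i <- i[which.min(cur$threshold[i])]
  list(threshold = cur$threshold[i], f1 = cur$f1[i], recall = cur$recall[i],
       precision = cur$precision[i], fallout = cur$fallout[i], curves = cur)
}

#' High-confidence cutoff from negative-set scores
#'
#' The smallest score above which no negative-set protein lies, i.e. the
#' maximum score attained by any negative-set protein. Scores strictly above
#' this cutoff carry no known false positives.
#'
#' @param scores_negatives Scores of the negative-set proteins.
#' @return The cutoff value.
#' @export
high_confidence_cutoff <- function(scores_negatives) {
  if (!length(scores_negatives) || all(is.na(scores_negatives))) {
    stop("no negative-set scores supplied", call. = FALSE)
  }
  max(scores_negatives, na.rm = TRUE)
}
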