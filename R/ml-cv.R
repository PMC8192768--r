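# Cross-validation harness, performance metrics and the Youden operating
# point. "tox" is always the positive class.

#' Rank-statistic AUC
#'
#' Probability that a random positive scores above a random negative, with
#' ties counted half — the Wilcoxon/Mann-Whitney form of the area under the
#' ROC curve, invariant under strictly monotone score transforms.
#'
#' @param scores numeric scores (higher = more toxic).
#' @param positive logical vector, `TRUE` for toxic items.
#' @return AUC in \[0, 1\] (`NA` if a class is empty).
#' @export
aucRank <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics from a confusion table
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy, balanced
#' accuracy (their mean) and F1 = 2TP/(2TP+FP+FN). A metric whose
#' denominator is zero is reported as `NA`, not 0. When scores are supplied
#' the rank-statistic AUC is included.
#'
#' @param tp,fp,tn,fn confusion counts (toxic is positive).
#' @param scores,positive optional pooled scores and truth for the AUC.
#' @return named list of metrics.
#' @export
computeMetrics <- function(tp, fp, tn, fn, scores = NULL, positive = NULL) {
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  se <- div(tp, tp + fn)
  sp <- div(tn, tn + fp)
  list(auc = if (is.null(scores)) NA_real_ else aucRank(scores, positive),
       sensitivity = se,
       specificity = sp,
       accuracy = div(tp + tn, tp + fp + tn + fn),
       balanced_accuracy = if (is.na(se) || is.na(sp)) NA_real_
                           else (se + sp) / 2,
       f1 = div(2 * tp, 2 * tp + fp + fn),
       confusion = c(TP = tp, FP = fp, TN = tn, FN = fn))
}

#' Youden index of an operating point
#'
#' `J = Se + Sp - 1`; the worked form used to report a chosen threshold.
#'
#' @param se,sp sensitivity and specificity.
#' @return the index.
#' @examples
#' youdenIndex(0.76, 0.82)  # 0.58
#' @export
youdenIndex <- function(se, sp) se + sp - 1

#' Optimal operating point by Youden's J
#'
#' Exhaustive scan over the unique score values as cutpoints (predict toxic
#' iff score >= c), maximizing J = Se(c) + Sp(c) - 1. Ties are broken toward
#' higher sensitivity, then lower threshold.
#'
#' @param scores numeric scores in \[0, 1\].
#' @param positive logical truth vector.
#' @return list: `threshold`, `J`, `sensitivity`, `specificity`.
#' @export
youdenOptimize <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0)
    stop("both classes are required to choose an operating point",
         call. = FALSE)
  cand <- sort(unique(scores))
  se <- vapply(cand, function(c) sum(scores[positive] >= c) / n1, numeric(1))
  sp <- vapply(cand, function(c) sum(scores[!positive] < c) / n0, numeric(1))
  J <- se + sp - 1
  best <- which(J == max(J))
  best <- best[order(-se[best], cand[best])][1]
  list(threshold = cand[best], J = J[best],
       sensitivity = se[best], specificity = sp[best])
}

## Stratified fold assignment: within each class, a seeded shuffle is dealt
## round-robin over folds. Returns an integer vector.
stratified_folds <- function(y, folds, seed) {
  assign <- integer(length(y))
  with_seed(seed, {
    for (cls in levels(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

## Core CV engine on a plain factor data.frame. Returns an ExperimentReport.
cv_run <- function(x, y, algorithm, smote = FALSE, folds = 10L, seed = 1L,
                   threshold = 0.5) {
  stopifnot(is.data.frame(x), folds >= 2)
  y <- factor(as.character(y), levels = c("nox", "tox"))
  if (any(table(y) < folds))
    al_log("WARN", "a class has fewer members than folds")
  fold_of <- stratified_folds(y, folds, seed)
  scores <- rep(NA_real_, length(y))
  per_fold <- vector("list", folds)
  smote_sources <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- fold_of != f
    if (nlevels(droplevels(y[tr])) < 2)
      stop("training fold ", f, " contains a single class; use fewer folds",
           call. = FALSE)
    xtr <- x[tr, , drop = FALSE]; ytr <- y[tr]
    if (smote) {
      bal <- with_seed(seed * 1000L + f, smoteNominal(xtr, ytr))
      train_ids <- which(tr)
      smote_sources[[f]] <- sort(unique(train_ids[unlist(bal$provenance)]))
      xtr <- bal$x; ytr <- bal$y
    }
    mdl <- with_seed(seed * 100L + f, train_backend(algorithm, xtr, ytr))
    te <- which(!tr)
    scores[te] <- predict_backend(mdl, x[te, , drop = FALSE])
    pos <- y[te] == "tox"
    pred <- scores[te] >= threshold
    per_fold[[f]] <- computeMetrics(sum(pred & pos), sum(pred & !pos),
                                    sum(!pred & !pos), sum(!pred & pos),
                                    scores[te], pos)
  }
  pos <- y == "tox"
  pred <- scores >= threshold
  m <- computeMetrics(sum(pred & pos), sum(pred & !pos),
                      sum(!pred & !pos), sum(!pred & pos), scores, pos)
  structure(list(
    config = list(algorithm = algorithm, smote = smote, folds = folds,
                  seed = seed, threshold = threshold,
                  n_features = ncol(x)),
    auc = m$auc, sensitivity = m$sensitivity, specificity = m$specificity,
    accuracy = m$accuracy, balanced_accuracy = m$balanced_accuracy,
    f1 = m$f1, confusion = m$confusion,
    per_fold = per_fold,
    youden = youdenOptimize(scores, pos),
    oof_scores = scores, truth = as.character(y), fold_of = fold_of,
    smote_sources = smote_sources), class = "ExperimentReport")
}

#' @export
print.ExperimentReport <- function(x, ...) {
  cat(sprintf(
    "ExperimentReport [%s%s, %d-fold CV, %d features]\n",
    x$config$algorithm, if (x$config$smote) " + SMOTE" else "",
    x$config$folds, x$config$n_features))
  cat(sprintf("  AUC %.3f | Se %.3f | Sp %.3f | Acc %.3f | BalAcc %.3f | F1 %.3f\n",
              x$auc, x$sensitivity, x$specificity, x$accuracy,
              x$balanced_accuracy, x$f1))
  cat(sprintf("  Youden J = %.3f at threshold %.3f (Se %.3f, Sp %.3f)\n",
              x$youden$J, x$youden$threshold, x$youden$sensitivity,
              x$youden$specificity))
  invisible(x)
}

## FeatureSet -> factor data.frame (sequences x features) with global
## per-feature level sets, safe column names, unknown-label rows dropped
## unless keep_unknown.
fs_to_df <- function(fs, keep_unknown = FALSE) {
  vals <- featureValues(fs)
  lab <- toxLabels(fs)
  keep <- if (keep_unknown) rep(TRUE, length(lab)) else lab != "unknown"
  df <- as.data.frame(lapply(seq_len(nrow(vals)), function(i)
    factor(vals[i, keep], levels = sort(unique(vals[i, ])))),
    col.names = paste0("F", seq_len(nrow(vals))))
  rownames(df) <- colnames(vals)[keep]
  attr(df, "feature_names") <- rownames(vals)
  list(x = df, y = lab[keep])
}

#' Cross-validate one experiment configuration
#'
#' Stratified k-fold cross-validation of a classifier on a categorical
#' feature matrix. When `smote = TRUE` the training portion of each fold is
#' balanced with [smoteNominal()] — synthetic rows are built from training
#' sequences only, never from the held-out fold. Out-of-fold scores are
#' pooled for the headline metrics and the Youden operating point.
#'
#' @param fs a [FeatureSet-class]; rows labeled `unknown` are excluded.
#' @param algorithm one of `"bayes_net"`, `"logistic"`, `"tree_j48_like"`,
#'   `"random_forest"`.
#' @param smote balance training folds.
#' @param folds number of folds (default 10).
#' @param seed integer controlling fold assignment, SMOTE and any stochastic
#'   learner.
#' @param threshold score cutoff for the confusion table (default 0.5).
#' @return an `ExperimentReport`: pooled and per-fold metrics, confusion
#'   counts, out-of-fold scores, Youden operating point, and (with SMOTE)
#'   the ids of training sequences that seeded synthetic samples per fold.
#' @export
crossValidate <- function(fs, algorithm = "random_forest", smote = FALSE,
                          folds = 10L, seed = 1L, threshold = 0.5) {
  d <- fs_to_df(fs)
  if (nlevels(droplevels(factor(d$y))) < 2)
    stop("feature matrix must contain both classes", call. = FALSE)
  rep <- cv_run(d$x, d$y, algorithm, smote, folds, seed, threshold)
  rep$sequence_ids <- rownames(d$x)
  rep
}
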