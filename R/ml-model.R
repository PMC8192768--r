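# Final model training and prediction: a trained backend plus everything
# needed to featurize a new sequence consistently (scheme universe, feature
# layout, per-feature level sets, operating threshold).

#' Train a toxicity classifier on the full dataset
#'
#' Fits the chosen backend on all labeled rows. The decision threshold is
#' taken from the Youden operating point of a cross-validation on the same
#' data (`cvThreshold = TRUE`), or fixed at 0.5.
#'
#' @param fs a [FeatureSet-class] (unknown rows excluded from fitting).
#' @param algorithm backend name (see [crossValidate()]).
#' @param smote balance the training data before fitting.
#' @param seed integer seed.
#' @param cvThreshold choose the threshold by cross-validated Youden scan.
#' @param folds folds for the threshold CV.
#' @param universe optional `positionUniverse()` data.frame, stored so new
#'   sequences can be encoded at prediction time.
#' @return a `ToxModel`.
#' @export
trainClassifier <- function(fs, algorithm = "random_forest", smote = FALSE,
                            seed = 1L, cvThreshold = FALSE, folds = 10L,
                            universe = NULL) {
  d <- fs_to_df(fs)
  y <- factor(as.character(d$y), levels = c("nox", "tox"))
  x <- d$x
  threshold <- 0.5
  if (cvThreshold) {
    rep <- cv_run(x, y, algorithm, smote, folds, seed)
    threshold <- rep$youden$threshold
  }
  if (smote) {
    bal <- with_seed(seed + 1L, smoteNominal(x, y))
    x <- bal$x; y <- bal$y
  }
  backend <- with_seed(seed, train_backend(algorithm, x, y))
  structure(list(backend = backend,
                 feature_info = featureInfo(fs),
                 threshold = threshold,
                 algorithm = algorithm,
                 universe = universe),
            class = "ToxModel")
}

#' @export
print.ToxModel <- function(x, ...) {
  cat(sprintf("ToxModel [%s, %d features, threshold %.3f]\n",
              x$algorithm, nrow(x$feature_info), x$threshold))
  invisible(x)
}

## One feature row (1-row data.frame, backend column names) from a token
## vector over the model's universe.
feature_row <- function(model, tokensVec, germlineId = NA_character_) {
  fi <- model$feature_info
  vals <- vapply(seq_len(nrow(fi)), function(i) {
    switch(fi$family[i],
           AMP = tokensVec[fi$pos1[i]],
           MAP = ,
           DAP = paste0(tokensVec[fi$pos1[i]], "-", tokensVec[fi$pos2[i]]),
           GLVJ = germlineId)
  }, character(1))
  df <- as.data.frame(as.list(vals),
                      col.names = paste0("F", seq_len(nrow(fi))),
                      stringsAsFactors = FALSE)
  df
}

#' Predict toxicity of encoded sequences
#'
#' Accepts either a [FeatureSet-class] whose features match the model's, or
#' a token matrix/vector over the model's scheme universe. The reported
#' confidence is the probability that the sequence is toxic; the label is
#' `tox` iff confidence >= the model's threshold.
#'
#' @param model a `ToxModel`.
#' @param newdata [FeatureSet-class], token matrix (positions x sequences)
#'   or single token vector.
#' @param germlineIds germline id(s) for the GLVJ feature when predicting
#'   from tokens.
#' @return data.frame: `sequence_id`, `confidence`, `label`.
#' @export
predictToxicity <- function(model, newdata, germlineIds = NA_character_) {
  if (is(newdata, "FeatureSet")) {
    if (!identical(featureInfo(newdata)$name, model$feature_info$name))
      stop("feature universe mismatch between model and data", call. = FALSE)
    d <- fs_to_df(newdata, keep_unknown = TRUE)
    x <- d$x
    ids <- rownames(x)
  } else {
    if (is.null(dim(newdata))) newdata <- as.matrix(newdata)
    gid <- rep_len(germlineIds, ncol(newdata))
    x <- do.call(rbind, lapply(seq_len(ncol(newdata)), function(k)
      feature_row(model, newdata[, k], gid[k])))
    ids <- colnames(newdata) %||% paste0("seq", seq_len(ncol(newdata)))
  }
  conf <- predict_backend(model$backend, x)
  data.frame(sequence_id = ids, confidence = conf,
             label = ifelse(conf >= model$threshold, "tox", "nox"),
             stringsAsFactors = FALSE)
}
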