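# Classifier backends. The four learners of the experiment grid map onto
# modern equivalents: naive Bayes (Bayesian-network surrogate), ridge
# logistic regression, pruned CART (a J48 stand-in) and random forest.
# Exact parameter parity with other ecosystems is not promised; the grid
# structure, evaluation protocol and metric definitions are.

ALGORITHMS <- c("bayes_net", "logistic", "tree_j48_like", "random_forest")

## One-hot expansion of a factor data.frame using its declared levels, so
## train and test designs always share columns. Drops nothing: constant
## columns are harmless to ridge regression.
one_hot <- function(df) {
  cols <- lapply(names(df), function(nm) {
    f <- df[[nm]]
    m <- outer(as.integer(f), seq_along(levels(f)), "==") * 1
    colnames(m) <- paste0(nm, "=", levels(f))
    m
  })
  do.call(cbind, cols)
}

train_backend <- function(algorithm, x, y) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  fit <- switch(algorithm,
    bayes_net = e1071::naiveBayes(x, y, laplace = 1),
    logistic = {
      mm <- one_hot(x)
      if (ncol(mm) < 2) mm <- cbind(mm, .pad = 0)
      glmnet::glmnet(mm, y, family = "binomial", alpha = 0,
                     lambda = c(1, 0.1, 0.01))
    },
    tree_j48_like = {
      d <- cbind(data.frame(.y = y), x)
      rpart::rpart(.y ~ ., data = d, method = "class")
    },
    random_forest = randomForest::randomForest(x, y, ntree = 100))
  structure(list(algorithm = algorithm, fit = fit,
                 xlevels = lapply(x, levels),
                 ## per-feature majority level: the fallback for categorical
                 ## values never seen in training
                 fallback = vapply(x, function(f)
                   names(sort(table(f), decreasing = TRUE))[1],
                   character(1))),
            class = "altox_backend")
}

## Probability of the positive class ("tox") for new rows; values outside the
## training vocabulary of a feature fall back to its majority level.
predict_backend <- function(model, newx) {
  ## a deserialized fit needs its package's S3 predict method registered
  pkg <- switch(model$algorithm, bayes_net = "e1071", logistic = "glmnet",
                tree_j48_like = "rpart", random_forest = "randomForest")
  requireNamespace(pkg, quietly = TRUE)
  for (nm in names(newx)) {
    v <- as.character(newx[[nm]])
    unseen <- !v %in% model$xlevels[[nm]]
    if (any(unseen)) v[unseen] <- model$fallback[[nm]]
    newx[[nm]] <- factor(v, levels = model$xlevels[[nm]])
  }
  p <- switch(model$algorithm,
    bayes_net = predict(model$fit, newx, type = "raw")[, "tox"],
    logistic = {
      mm <- one_hot(newx)
      if (ncol(mm) < 2) mm <- cbind(mm, .pad = 0)
      as.numeric(predict(model$fit, mm, s = 0.01, type = "response"))
    },
    tree_j48_like = predict(model$fit, newx, type = "prob")[, "tox"],
    random_forest = predict(model$fit, newx, type = "prob")[, "tox"])
  unname(p)
}
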