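# Metrics, Youden scan, information gain, SMOTE, cross-validation and grid.

test_that("metrics follow their defining formulas", {
  m <- computeMetrics(3, 2, 8, 1)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$accuracy, 11 / 14)
  expect_equal(m$balanced_accuracy, 0.775)
  expect_equal(m$f1, 6 / 9)
  # undefined metrics are missing, not zero
  m <- computeMetrics(0, 2, 8, 0)
  expect_true(is.na(m$sensitivity))
  expect_true(is.na(m$balanced_accuracy))
})

test_that("rank AUC is tie-aware and transform-invariant", {
  pos <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(aucRank(c(0.9, 0.8, 0.2, 0.1), pos), 1)
  expect_equal(aucRank(c(0.5, 0.5, 0.5, 0.5), pos), 0.5)
  withr::with_seed(17, {
    s <- runif(50); y <- runif(50) > 0.5
    expect_equal(aucRank(s, y), aucRank(qlogis(s / 2 + 0.25), y))
    # cross-check against an independent ROC implementation
    skip_if_not_installed("pROC")
    expect_equal(aucRank(s, y),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                direction = "<",
                                                levels = c(FALSE, TRUE)))))
  })
})

test_that("Youden scan equals brute force and reports the worked value", {
  expect_equal(youdenIndex(0.76, 0.82), 0.58)
  withr::with_seed(23, {
    for (k in 1:20) {
      n <- sample(8:30, 1)
      s <- round(runif(n), 2)
      y <- runif(n) > 0.4
      if (!any(y) || all(y)) next
      opt <- youdenOptimize(s, y)
      expect_equal(opt$J, enum_youden_J(s, y))
      expect_equal(opt$J, opt$sensitivity + opt$specificity - 1)
      expect_gte(opt$J, -1); expect_lte(opt$J, 1)
    }
  })
  # perfectly separating scores reach J = 1
  opt <- youdenOptimize(c(0.9, 0.8, 0.1), c(TRUE, TRUE, FALSE))
  expect_equal(opt$J, 1)
})

test_that("information gain matches hand-computed entropies", {
  y <- rep(c("tox", "nox"), each = 5)
  # feature identical to the label: IG = H(Y) = 1 bit
  expect_equal(infoGain(y == "tox", y), 1)
  # constant feature: zero
  expect_equal(infoGain(rep("a", 10), y), 0)
  # 3-level feature, hand-computed conditional entropy
  x <- c("a", "a", "a", "b", "b", "c", "c", "c", "b", "b")
  # y:  t    t    t    t    t    n    n    n    n    n
  h <- function(p) ifelse(p %in% c(0, 1), 0, -p * log2(p) - (1 - p) * log2(1 - p))
  expected <- 1 - (0.3 * h(1) + 0.4 * h(2 / 4) + 0.3 * h(0))
  expect_equal(infoGain(x, y), expected, tolerance = 1e-12)
  expect_gte(infoGain(x, y), 0)
})

test_that("value-level ranking filters by cutoff and orders by gain", {
  d <- planted_dataset(seed = 42)
  fs <- assembleFeatureMatrix(d$sme, "AMP")
  rk <- infoGainRank(fs, cutoff = 0.01)
  expect_true(all(rk$info_gain_bits >= 0.01))
  expect_equal(rk$general_rank, seq_len(nrow(rk)))
  expect_true(!is.unsorted(-rk$info_gain_bits))
  expect_equal(rk$name[1], "49-A")
  # occurrence columns count carriers per class
  i <- which(rk$name == "49-A")
  tok <- tokens(d$sme); lab <- toxLabels(d$sme)
  expect_equal(rk$count_tox[i], sum(tok[49, lab == "tox"] == "A"))
  expect_equal(rk$count_nox[i], sum(tok[49, lab == "nox"] == "A"))
})

test_that("nominal SMOTE balances classes and tracks provenance", {
  withr::with_seed(3, {
    x <- data.frame(
      f1 = factor(sample(c("A", "X"), 30, TRUE, prob = c(0.3, 0.7)),
                  levels = c("A", "X")),
      f2 = factor(sample(c("E", "X"), 30, TRUE), levels = c("E", "X")))
    y <- factor(rep(c("tox", "nox"), c(10, 20)), levels = c("nox", "tox"))
    bal <- smoteNominal(x, y)
    expect_equal(unname(table(bal$y)["tox"]), unname(table(bal$y)["nox"]))
    expect_equal(length(bal$provenance), 10)
    # every contributing row is a minority row of the input
    expect_true(all(unlist(bal$provenance) %in% which(y == "tox")))
    # synthetic values are legal levels
    expect_true(all(as.character(bal$x$f1) %in% levels(x$f1)))
  })
})

test_that("cross-validation recovers separable signal and respects folds", {
  d <- planted_dataset(seed = 42, p_tox = 1, p_nox = 0)
  fs <- assembleFeatureMatrix(d$sme, "AMP")
  rep <- crossValidate(fs, "tree_j48_like", folds = 5, seed = 1)
  expect_equal(rep$auc, 1.0, tolerance = 0.02)
  # every sequence is scored exactly once out-of-fold
  expect_false(anyNA(rep$oof_scores))
  expect_equal(length(rep$oof_scores), ncol(fs))
  expect_equal(sort(unique(rep$fold_of)), 1:5)
  # reproducibility: same seed, same report
  rep2 <- crossValidate(fs, "tree_j48_like", folds = 5, seed = 1)
  expect_identical(rep$oof_scores, rep2$oof_scores)
})

test_that("all four backends produce valid probabilities", {
  d <- planted_dataset(n_tox = 40, n_nox = 50, seed = 7)
  fs <- assembleFeatureMatrix(d$sme, "AMP")
  for (alg in c("bayes_net", "logistic", "tree_j48_like", "random_forest")) {
    rep <- crossValidate(fs, alg, folds = 4, seed = 2)
    expect_true(all(rep$oof_scores >= 0 & rep$oof_scores <= 1), info = alg)
    expect_gt(rep$auc, 0.7)  # strong planted signal
  }
})

test_that("SMOTE inside CV balances training folds without touching tests", {
  d <- planted_dataset(n_tox = 30, n_nox = 60, seed = 11)
  fs <- assembleFeatureMatrix(d$sme, "AMP")
  rep <- crossValidate(fs, "bayes_net", smote = TRUE, folds = 5, seed = 4)
  for (f in 1:5) {
    test_ids <- which(rep$fold_of == f)
    expect_length(intersect(rep$smote_sources[[f]], test_ids), 0)
  }
})

test_that("the experiment grid enumerates 7 x 4 x 2 configurations", {
  g <- gridConfigurations()
  expect_equal(nrow(g), 56)
  expect_equal(sum(!g$smote), 28)
  expect_equal(length(unique(g$families)), 7)
  expect_equal(nrow(gridConfigurations(algorithms = "logistic")), 14)
})

test_that("a reduced grid run returns coherent results and flags a best row", {
  d <- planted_dataset(n_tox = 30, n_nox = 40, seed = 5)
  ts <- generateToyStructure(47:52, interfacePositions = 49,
                             monomericPairs = rbind(c(48, 50)))
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(ts$pdb, f)
  co <- loadStructureCbeta(f, c("A", "B"))
  cm <- buildContactMap(co$A, co$B, ts$map)
  out <- runGrid(d$sme, cm, algorithms = "bayes_net", smote = FALSE,
                 folds = 4, seed = 1)
  expect_equal(nrow(out$results), 7)
  expect_equal(sum(out$results$best), 1)
  expect_true(all(out$results$auc >= 0 & out$results$auc <= 1))
})

test_that("incremental top-feature trajectories grow nested classifiers", {
  d <- planted_dataset(seed = 42)
  fs <- assembleFeatureMatrix(d$sme, "AMP")
  rk <- infoGainRank(fs)
  traj <- suppressWarnings(
    incrementalFeatureExperiment(fs, rk, kPerFamily = 3,
                                 algorithm = "tree_j48_like", folds = 4,
                                 seed = 2))
  expect_equal(traj$k, seq_len(nrow(traj)))
  expect_lte(nrow(traj), 3)
  expect_equal(traj$added_feature[1], rk$name[1])
  # the top planted feature alone already separates well here
  expect_gt(traj$auc[1], 0.7)
})

test_that("prediction from tokens matches prediction from the feature set", {
  d <- planted_dataset(seed = 42)
  fs <- assembleFeatureMatrix(d$sme, "AMP")
  model <- trainClassifier(fs, "bayes_net", seed = 1,
                           universe = positionUniverse(d$sme))
  p1 <- predictToxicity(model, fs)
  p2 <- predictToxicity(model, tokens(d$sme))
  expect_equal(p1$confidence, p2$confidence)
  expect_true(all(p1$confidence >= 0 & p1$confidence <= 1))
  # germline itself (all-X tokens) gets a valid probability
  allx <- rep("X", nrow(tokens(d$sme)))
  p3 <- predictToxicity(model, allx)
  expect_true(p3$confidence >= 0 && p3$confidence <= 1)
})
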