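# The experiment grid, information-gain feature ranking and the control
# experiments (random-label null, incremental top-feature trajectory).

FAMILY_SUBSETS <- list("AMP", "MAP", "DAP",
                       c("AMP", "MAP"), c("AMP", "DAP"), c("MAP", "DAP"),
                       c("AMP", "MAP", "DAP"))

#' Enumerate the experiment grid
#'
#' All non-empty subsets of the three feature families (2^3 - 1 = 7) crossed
#' with the four learning algorithms gives 28 feature/algorithm
#' configurations; each runs with and without SMOTE for 56 experiments in
#' total. Ordering is deterministic.
#'
#' @param algorithms algorithms to include (default all four).
#' @param smote SMOTE settings to include (default both).
#' @return data.frame: `families` (e.g. `"AMP+MAP"`), `algorithm`, `smote`.
#' @export
gridConfigurations <- function(algorithms = ALGORITHMS,
                               smote = c(FALSE, TRUE)) {
  grid <- expand.grid(smote = smote,
                      algorithm = algorithms,
                      fam = seq_along(FAMILY_SUBSETS),
                      stringsAsFactors = FALSE)
  data.frame(families = vapply(FAMILY_SUBSETS[grid$fam], paste,
                               character(1), collapse = "+"),
             algorithm = grid$algorithm,
             smote = grid$smote,
             stringsAsFactors = FALSE)
}

#' Run the full experiment grid
#'
#' Cross-validates every configuration from [gridConfigurations()] on the
#' dataset and flags the best by AUC (ties broken by configuration order).
#'
#' @param sme a [SMutExperiment-class].
#' @param contactMap a [ContactMap-class].
#' @param algorithms,smote optional restrictions of the grid.
#' @param folds,seed cross-validation settings.
#' @return list: `results` (one row per configuration with the six metrics
#'   and a `best` flag) and `reports` (the `ExperimentReport` objects).
#' @export
runGrid <- function(sme, contactMap, algorithms = ALGORITHMS,
                    smote = c(FALSE, TRUE), folds = 10L, seed = 1L) {
  cfg <- gridConfigurations(algorithms, smote)
  fams <- strsplit(cfg$families, "+", fixed = TRUE)
  fsets <- list()
  reports <- vector("list", nrow(cfg))
  rows <- vector("list", nrow(cfg))
  for (k in seq_len(nrow(cfg))) {
    key <- cfg$families[k]
    if (is.null(fsets[[key]]))
      fsets[[key]] <- assembleFeatureMatrix(sme, fams[[k]], contactMap)
    al_log("INFO", "grid ", k, "/", nrow(cfg), ": ", key, " / ",
           cfg$algorithm[k], if (cfg$smote[k]) " + SMOTE" else "")
    rep <- crossValidate(fsets[[key]], cfg$algorithm[k], cfg$smote[k],
                         folds, seed)
    reports[[k]] <- rep
    rows[[k]] <- data.frame(
      families = key, algorithm = cfg$algorithm[k], smote = cfg$smote[k],
      auc = rep$auc, sensitivity = rep$sensitivity,
      specificity = rep$specificity, accuracy = rep$accuracy,
      balanced_accuracy = rep$balanced_accuracy, f1 = rep$f1,
      stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows)
  results$best <- seq_len(nrow(results)) == which.max(results$auc)
  list(results = results, reports = reports)
}

#' Information gain of a categorical feature for a class label
#'
#' `IG = H(Y) - H(Y | X)` with base-2 entropies; zero for a constant or
#' uninformative feature, `H(Y)` for a feature identical to the label.
#'
#' @param x categorical vector (any number of levels).
#' @param y class labels.
#' @return information gain in bits (never negative).
#' @export
infoGain <- function(x, y) {
  H <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  hy <- H(table(y) / length(y))
  tab <- table(x, y)
  px <- rowSums(tab) / sum(tab)
  hygx <- sum(px * apply(tab, 1, function(r)
    if (sum(r) == 0) 0 else H(r / sum(r))))
  max(0, hy - hygx)
}

#' Rank value-level features by information gain
#'
#' Each categorical feature is expanded into its observed (feature, token)
#' indicator variables — the `49-A` / `56X-59X` style variables of the
#' original nominal-attribute setting — and each indicator is scored by
#' [infoGain()] against the tox/nox label. Indicators below `cutoff` bits
#' are removed. Ranks are 1-based, ties broken by name; `family_rank` ranks
#' within a family and `general_rank` across all families.
#'
#' @param fs a [FeatureSet-class] (unknown-label rows are ignored).
#' @param cutoff minimum information gain kept (default 0.01 bits).
#' @return data.frame: `name` (e.g. `"49-A"`), `family`, `pos1`, `pos2`,
#'   `level`, `info_gain_bits`, `count_tox`, `count_nox`, `family_rank`,
#'   `general_rank`.
#' @export
infoGainRank <- function(fs, cutoff = 0.01) {
  vals <- featureValues(fs)
  lab <- toxLabels(fs)
  keep <- lab != "unknown"
  vals <- vals[, keep, drop = FALSE]
  y <- lab[keep]
  rd <- featureInfo(fs)
  out <- vector("list", nrow(vals))
  for (i in seq_len(nrow(vals))) {
    v <- vals[i, ]
    lev <- sort(unique(v))
    fam <- rd$family[i]
    nm <- vapply(lev, function(l) {
      if (fam == "AMP") paste0(rd$pos1[i], "-", l)
      else if (fam == "GLVJ") l
      else {
        tk <- strsplit(l, "-", fixed = TRUE)[[1]]
        paste0(rd$pos1[i], tk[1], "-", rd$pos2[i], tk[2])
      }
    }, character(1))
    ig <- vapply(lev, function(l) infoGain(v == l, y), numeric(1))
    out[[i]] <- data.frame(
      name = nm, family = fam, pos1 = rd$pos1[i], pos2 = rd$pos2[i],
      level = lev,
      info_gain_bits = ig,
      count_tox = vapply(lev, function(l) sum(v == l & y == "tox"),
                         numeric(1)),
      count_nox = vapply(lev, function(l) sum(v == l & y == "nox"),
                         numeric(1)),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  tab <- do.call(rbind, out)
  tab <- tab[tab$info_gain_bits >= cutoff, , drop = FALSE]
  tab <- tab[order(-tab$info_gain_bits, tab$name), , drop = FALSE]
  tab$general_rank <- seq_len(nrow(tab))
  tab$family_rank <- stats::ave(seq_len(nrow(tab)), tab$family,
                                FUN = seq_along)
  rownames(tab) <- NULL
  tab
}

## Indicator data.frame ("yes"/"no" factors) for a set of ranked value-level
## features, in ranking order.
indicator_df <- function(fs, ranked) {
  vals <- featureValues(fs)
  rd <- featureInfo(fs)
  key <- function(fam, p1, p2) paste(fam, p1, p2)
  row_of <- setNames(seq_len(nrow(rd)), key(rd$family, rd$pos1, rd$pos2))
  cols <- lapply(seq_len(nrow(ranked)), function(k) {
    i <- row_of[[key(ranked$family[k], ranked$pos1[k], ranked$pos2[k])]]
    factor(ifelse(vals[i, ] == ranked$level[k], "yes", "no"),
           levels = c("no", "yes"))
  })
  df <- as.data.frame(cols, col.names = paste0("F", seq_len(nrow(ranked))))
  rownames(df) <- colnames(vals)
  df
}

#' Incremental top-feature experiment
#'
#' Takes the `kPerFamily` best features of each family from an
#' information-gain ranking, orders the union by general rank, and
#' cross-validates one classifier per nested prefix — 30 classifiers when
#' all three families contribute 10. The AUC/accuracy trajectory shows how
#' much signal the top features alone carry.
#'
#' @param fs a [FeatureSet-class].
#' @param ranked output of [infoGainRank()].
#' @param kPerFamily features kept per family (fewer are used, with a
#'   warning, if a family has fewer ranked features).
#' @param algorithm,smote,folds,seed passed to the CV engine.
#' @return data.frame: `k`, `added_feature`, `family`, `auc`, `accuracy`.
#' @export
incrementalFeatureExperiment <- function(fs, ranked, kPerFamily = 10L,
                                         algorithm = "random_forest",
                                         smote = FALSE, folds = 10L,
                                         seed = 1L) {
  top <- do.call(rbind, lapply(split(ranked, ranked$family), function(d)
    d[d$family_rank <= kPerFamily, , drop = FALSE]))
  if (nrow(top) < kPerFamily * length(unique(ranked$family)))
    warning("fewer ranked features than requested; trajectory shortened")
  top <- top[order(top$general_rank), , drop = FALSE]
  lab <- toxLabels(fs)
  keep <- lab != "unknown"
  df_all <- indicator_df(fs, top)[keep, , drop = FALSE]
  y <- lab[keep]
  rows <- vector("list", nrow(top))
  for (k in seq_len(nrow(top))) {
    rep <- cv_run(df_all[, seq_len(k), drop = FALSE], y, algorithm, smote,
                  folds, seed)
    rows[[k]] <- data.frame(k = k, added_feature = top$name[k],
                            family = top$family[k], auc = rep$auc,
                            accuracy = rep$accuracy,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Random-label overfitting control
#'
#' Takes all sequences of one class, randomly relabels half of them as the
#' opposite class, and cross-validates. Any apparent signal is then pure
#' overfitting, so a sound protocol must score close to AUC 0.5.
#'
#' @param fs a [FeatureSet-class].
#' @param whichClass class to subset (default `"tox"`).
#' @param algorithm,smote,folds passed to the CV engine.
#' @param seed controls both the relabeling and the CV.
#' @return an `ExperimentReport` with an extra `relabeled_ids` element.
#' @export
randomLabelControl <- function(fs, whichClass = "tox",
                               algorithm = "random_forest", smote = FALSE,
                               folds = 10L, seed = 1L) {
  d <- fs_to_df(fs)
  idx <- which(d$y == whichClass)
  if (length(idx) < 2 * folds)
    stop("class too small for a ", folds, "-fold control", call. = FALSE)
  other <- if (whichClass == "tox") "nox" else "tox"
  flip <- with_seed(seed, sort(sample(idx, floor(length(idx) / 2))))
  y <- rep(whichClass, length(idx))
  names(y) <- rownames(d$x)[idx]
  y[as.character(names(y)) %in% rownames(d$x)[flip]] <- other
  rep <- cv_run(d$x[idx, , drop = FALSE], y, algorithm, smote, folds, seed)
  rep$relabeled_ids <- rownames(d$x)[flip]
  rep
}
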