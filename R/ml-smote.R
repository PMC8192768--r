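# Nominal-feature SMOTE: oversample the minority class with synthetic
# instances built from the k nearest minority neighbours under Hamming
# distance, each categorical value taken by majority vote among those
# neighbours. Interpolation is meaningless for nominal attributes, so the
# vote replaces it.

#' Balance a nominal training set by synthetic minority oversampling
#'
#' Adds synthetic minority-class rows until the two classes are equal in
#' size. For each synthetic row a random minority instance is chosen as
#' base; its `k` nearest minority neighbours (Hamming distance over the
#' categorical columns, ties by row order) vote per feature, ties resolved
#' toward the base instance's value, then alphabetically. Only the rows in
#' `x` can contribute — callers applying this inside a cross-validation fold
#' therefore never leak held-out sequences into the synthetic samples.
#'
#' @param x data.frame of factor columns (the training fold).
#' @param y factor of class labels for `x` (two classes).
#' @param k number of voting neighbours.
#' @return list: `x` and `y` augmented with the synthetic rows, and
#'   `provenance` — for each synthetic row, the integer indices (into the
#'   input `x`) of its base instance and voting neighbours.
#' @export
smoteNominal <- function(x, y, k = 5) {
  stopifnot(is.data.frame(x), nlevels(droplevels(y)) == 2)
  tabs <- table(y)
  tabs <- tabs[tabs > 0]
  minority <- names(tabs)[which.min(tabs)]
  need <- max(tabs) - min(tabs)
  if (need == 0)
    return(list(x = x, y = y, provenance = list()))
  min_idx <- which(y == minority)
  if (length(min_idx) < 2)
    stop("minority class too small for SMOTE", call. = FALSE)
  X <- as.matrix(as.data.frame(lapply(x, as.character),
                               stringsAsFactors = FALSE))[min_idx, ,
                                                          drop = FALSE]
  kk <- min(k, length(min_idx) - 1)
  synth <- vector("list", need)
  prov <- vector("list", need)
  for (s in seq_len(need)) {
    b <- sample.int(length(min_idx), 1)
    d <- rowSums(X != matrix(X[b, ], nrow(X), ncol(X), byrow = TRUE))
    d[b] <- Inf
    nn <- order(d)[seq_len(kk)]
    vals <- vapply(seq_len(ncol(X)), function(f) {
      tab <- table(X[nn, f])
      maj <- names(tab)[tab == max(tab)]
      if (X[b, f] %in% maj) X[b, f] else sort(maj)[1]
    }, character(1))
    synth[[s]] <- vals
    prov[[s]] <- min_idx[c(b, nn)]
  }
  sx <- as.data.frame(do.call(rbind, synth), stringsAsFactors = FALSE)
  names(sx) <- names(x)
  for (nm in names(x)) sx[[nm]] <- factor(sx[[nm]], levels = levels(x[[nm]]))
  out_x <- rbind(x, sx)
  rownames(out_x) <- NULL
  out_y <- factor(c(as.character(y), rep(minority, need)), levels = levels(y))
  list(x = out_x, y = out_y, provenance = prov)
}
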