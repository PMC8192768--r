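# Feature families: AMP (token at each scheme position), MAP/DAP (token
# pairs at monomeric / dimeric structural contacts) and the optional GLVJ
# (germline V-J rearrangement) baseline feature.

#' Per-position amino-acid features (AMP)
#'
#' One categorical value per scheme position: the somatically mutated residue,
#' `"X"` where the sequence matches its germline, `"."` where uncovered.
#'
#' @param tokensMat positions-by-sequences token matrix (see [tokens()]).
#' @return the same matrix with AMP row names (the position numbers).
#' @export
extractAMP <- function(tokensMat) {
  rownames(tokensMat) <- as.character(seq_len(nrow(tokensMat)))
  tokensMat
}

#' Contact-pair features (MAP / DAP)
#'
#' For each contact pair \{i, j\} (i <= j) the value is the position-i token,
#' a dash, and the position-j token, e.g. `"A-X"` for a mutation to alanine
#' at i with an unmutated j, or `"X-X"` for an unmutated pair.
#'
#' @param tokensMat positions-by-sequences token matrix.
#' @param pairs two-column integer matrix of scheme-position pairs.
#' @return character matrix, one row per pair, named `"i-j"`.
#' @export
extractPairFamily <- function(tokensMat, pairs) {
  if (!nrow(pairs)) {
    out <- matrix(character(0), 0, ncol(tokensMat))
    colnames(out) <- colnames(tokensMat)
    return(out)
  }
  if (max(pairs) > nrow(tokensMat))
    stop("contact pair position outside the scheme universe", call. = FALSE)
  out <- matrix(paste(tokensMat[pairs[, 1], , drop = FALSE],
                      tokensMat[pairs[, 2], , drop = FALSE], sep = "-"),
                nrow = nrow(pairs),
                dimnames = list(paste0(pairs[, 1], "-", pairs[, 2]),
                                colnames(tokensMat)))
  out
}

#' Assemble the labeled categorical feature matrix
#'
#' Stacks the selected feature families into a [FeatureSet-class], one column
#' block per family in the order AMP, MAP, DAP, GLVJ. Rows with label
#' `unknown` are kept (they are excluded from training by the harness, not
#' here). Assembly is deterministic: identical inputs give identical objects.
#'
#' @param sme a [SMutExperiment-class].
#' @param families non-empty subset of `c("AMP", "MAP", "DAP", "GLVJ")`.
#' @param contactMap a [ContactMap-class]; required when MAP or DAP selected.
#' @return a [FeatureSet-class].
#' @export
assembleFeatureMatrix <- function(sme, families = c("AMP", "MAP", "DAP"),
                                  contactMap = NULL) {
  families <- match.arg(families, c("AMP", "MAP", "DAP", "GLVJ"),
                        several.ok = TRUE)
  if (!length(families)) stop("families must be non-empty", call. = FALSE)
  if (any(c("MAP", "DAP") %in% families) && is.null(contactMap))
    stop("MAP/DAP features require a contact map", call. = FALSE)
  tok <- tokens(sme)
  blocks <- list(); info <- list()
  if ("AMP" %in% families) {
    amp <- extractAMP(tok)
    blocks$AMP <- amp
    info$AMP <- data.frame(family = "AMP", name = rownames(amp),
                           pos1 = seq_len(nrow(amp)), pos2 = NA_integer_)
  }
  for (fam in c("MAP", "DAP")) {
    if (!fam %in% families) next
    prs <- if (fam == "MAP") monomericPairs(contactMap) else
      dimericPairs(contactMap)
    blk <- extractPairFamily(tok, prs)
    blocks[[fam]] <- blk
    info[[fam]] <- data.frame(
      family = rep(fam, nrow(prs)),
      name = if (nrow(prs)) paste0(fam, ":", rownames(blk)) else character(0),
      pos1 = as.integer(prs[, 1]),
      pos2 = as.integer(prs[, 2]))
  }
  if ("GLVJ" %in% families) {
    blocks$GLVJ <- matrix(colData(sme)$germline_id, nrow = 1,
                          dimnames = list("GLVJ", colnames(sme)))
    info$GLVJ <- data.frame(family = "GLVJ", name = "GLVJ",
                            pos1 = NA_integer_, pos2 = NA_integer_)
  }
  values <- do.call(rbind, unname(blocks))
  rd <- do.call(rbind, unname(info))
  rownames(values) <- rd$name
  se <- SummarizedExperiment(
    assays = list(values = values),
    rowData = DataFrame(rd),
    colData = DataFrame(label = toxLabels(sme), row.names = colnames(sme)))
  new("FeatureSet", se)
}
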