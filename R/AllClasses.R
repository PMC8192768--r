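#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importClassesFrom Biostrings AAStringSet
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

# ---------------------------------------------------------------------------
# GermlineSet: germline V-J reference sequences with per-residue
# Kabat-Chothia labels (number plus optional insertion letter, e.g. "30A").
# ---------------------------------------------------------------------------

#' Germline reference set
#'
#' Holds the unmutated germline (V-J rearrangement) amino-acid sequences that
#' mature light chains are compared against, together with one Kabat-Chothia
#' label per residue. Labels carry the structural alignment information that
#' lets light chains of different lengths be compared position by position.
#'
#' @slot sequences [Biostrings::AAStringSet] named by germline id.
#' @slot kcLabels named list, one character vector of Kabat-Chothia labels per
#'   germline, `length == width(sequences)`; strictly increasing under Kabat
#'   ordering (numeric part, then insertion letter).
#' @export
setClass("GermlineSet",
  representation(sequences = "AAStringSet", kcLabels = "list"))

setValidity("GermlineSet", function(object) {
  ids <- names(object@sequences)
  if (is.null(ids) || anyDuplicated(ids))
    return("germline ids must be unique and non-empty")
  if (!identical(ids, names(object@kcLabels)))
    return("kcLabels must be named identically to sequences")
  for (id in ids) {
    n <- Biostrings::width(object@sequences[id])
    lab <- object@kcLabels[[id]]
    if (length(lab) != n)
      return(sprintf("germline '%s': %d labels for %d residues", id,
                     length(lab), n))
    key <- kabat_rank(lab)
    if (any(diff(key) <= 0))
      return(sprintf("germline '%s': labels not strictly increasing", id))
  }
  TRUE
})

#' Construct a [GermlineSet-class]
#'
#' @param ids character vector of germline (V-J rearrangement) identifiers.
#' @param sequences character vector of amino-acid sequences.
#' @param kcLabels list of character vectors of Kabat-Chothia labels, one per
#'   residue of the matching sequence.
#' @return A [GermlineSet-class].
#' @examples
#' gl <- GermlineSet("GLV1:GLJ1", "SYVLTQPP",
#'                   list(as.character(1:8)))
#' germlineIds(gl)
#' @export
GermlineSet <- function(ids, sequences, kcLabels) {
  seqs <- Biostrings::AAStringSet(setNames(toupper(sequences), ids))
  new("GermlineSet", sequences = seqs, kcLabels = setNames(kcLabels, ids))
}

setMethod("show", "GermlineSet", function(object) {
  cat(sprintf("GermlineSet with %d germlines\n", length(object@sequences)))
  for (id in head(germlineIds(object), 5))
    cat(sprintf("  %s (%d aa)\n", id, Biostrings::width(object@sequences[id])))
  if (length(object@sequences) > 5) cat("  ...\n")
})

# ---------------------------------------------------------------------------
# ContactMap: monomeric and dimeric residue-contact pair sets in scheme
# positions, derived from C-beta distances in a homodimeric structure.
# ---------------------------------------------------------------------------

#' Residue contact map of a light-chain homodimer
#'
#' Unordered scheme-position pairs whose C-beta atoms lie strictly closer than
#' `threshold` angstroms, split into within-chain (monomeric) and chain-crossing
#' (dimeric) sets. Dimeric pairs may pair a position with itself on the
#' opposite chain; monomeric pairs may not.
#'
#' @slot monomeric integer matrix, 2 columns, rows sorted, i < j.
#' @slot dimeric integer matrix, 2 columns, i <= j.
#' @slot threshold numeric, contact cutoff in angstroms (strict `<`).
#' @slot structureId character, e.g. a PDB id.
#' @slot chainPair character of length 2.
#' @export
setClass("ContactMap",
  representation(monomeric = "matrix", dimeric = "matrix",
                 threshold = "numeric", structureId = "character",
                 chainPair = "character"))

setValidity("ContactMap", function(object) {
  if (object@threshold <= 0) return("threshold must be positive")
  for (nm in c("monomeric", "dimeric")) {
    m <- slot(object, nm)
    if (ncol(m) != 2) return(sprintf("%s must have 2 columns", nm))
    if (nrow(m) && any(m[, 1] > m[, 2]))
      return(sprintf("%s pairs must satisfy i <= j", nm))
  }
  if (nrow(object@monomeric) &&
      any(object@monomeric[, 1] == object@monomeric[, 2]))
    return("monomeric pairs may not pair a position with itself")
  TRUE
})

setMethod("show", "ContactMap", function(object) {
  cat(sprintf(
    "ContactMap [%s, chains %s|%s, Cb < %.2f A]: %d monomeric, %d dimeric pairs\n",
    object@structureId, object@chainPair[1], object@chainPair[2],
    object@threshold, nrow(object@monomeric), nrow(object@dimeric)))
})

# ---------------------------------------------------------------------------
# SMutExperiment: per-position somatic-mutation tokens for a dataset,
# positions x sequences, built on SummarizedExperiment.
# ---------------------------------------------------------------------------

#' Somatic-mutation encodings of a light-chain dataset
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single assay `tokens`
#' is a character matrix (scheme positions x sequences). A cell holds the
#' mature-chain residue where it differs from the germline (a somatic
#' mutation), `"X"` where it matches, and `"."` where the sequence does not
#' cover the position. `rowData` carries `position` (progressive 1..N) and
#' `kc_label`; `colData` carries `label` (tox/nox/unknown), `germline_id` and
#' `n_sm` (somatic mutations per sequence).
#'
#' @export
setClass("SMutExperiment", contains = "SummarizedExperiment")

setValidity("SMutExperiment", function(object) {
  if (!"tokens" %in% SummarizedExperiment::assayNames(object))
    return("assay 'tokens' is required")
  tok <- assay(object, "tokens")
  if (!is.character(tok)) return("tokens must be a character matrix")
  if (nrow(tok) && !all(tok %in% smutTokens()))
    return("tokens outside the encoding vocabulary")
  cd <- colData(object)
  need <- c("label", "germline_id", "n_sm")
  if (!all(need %in% colnames(cd)))
    return(paste("colData must contain", paste(need, collapse = ", ")))
  if (nrow(cd) && !all(cd$label %in% c("tox", "nox", "unknown")))
    return("labels must be in {tox, nox, unknown}")
  n_sm <- colSums(matrix(tok %in% AA_CODES, nrow = nrow(tok)))
  if (nrow(cd) && !all(n_sm == cd$n_sm))
    return("n_sm inconsistent with tokens")
  TRUE
})

# ---------------------------------------------------------------------------
# FeatureSet: categorical feature matrix (features x sequences).
# ---------------------------------------------------------------------------

#' Categorical feature matrix for classification
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose assay `values` is a
#' character matrix of categorical tokens, one row per feature. `rowData`
#' carries `family` (AMP, MAP, DAP or GLVJ), `name`, and the scheme positions
#' `pos1`/`pos2` the feature reads (NA where not applicable). `colData`
#' carries the tox/nox/unknown `label`.
#'
#' @export
setClass("FeatureSet", contains = "SummarizedExperiment")

setValidity("FeatureSet", function(object) {
  if (!"values" %in% SummarizedExperiment::assayNames(object))
    return("assay 'values' is required")
  rd <- rowData(object)
  if (!all(c("family", "name", "pos1", "pos2") %in% colnames(rd)))
    return("rowData must contain family, name, pos1, pos2")
  if (nrow(rd) && !all(rd$family %in% c("AMP", "MAP", "DAP", "GLVJ")))
    return("unknown feature family")
  if (!"label" %in% colnames(colData(object)))
    return("colData must contain label")
  TRUE
})
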