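# S_mut encoding: each light chain expressed as its somatic-mutation
# difference from the germline ("X" where identical, the mature residue where
# mutated, "." where the position is not covered).

#' Somatic-mutation encoding of one sequence pair
#'
#' Aligns a light chain to its germline and encodes the per-position
#' difference: `"X"` where the residues agree and the mature-chain residue
#' where they differ. `"SYELTQPP"` against germline `"SYVLTQPP"` encodes as
#' `"XXEXXXXX"` (one somatic mutation, V to E, at position 3).
#'
#' @param lcSeq,glSeq amino-acid strings.
#' @param ... scoring arguments passed to [globalAlign()].
#' @return list with `tokens` (character vector over germline positions,
#'   `"."` where the light chain leaves a germline position uncovered),
#'   `string` (tokens collapsed), and `nSM`.
#' @examples
#' smutEncoding("SYELTQPP", "SYVLTQPP")$string  # "XXEXXXXX"
#' @export
smutEncoding <- function(lcSeq, glSeq, ...) {
  smut_from_alignment(globalAlign(lcSeq, glSeq, ...))
}

## encoding from an existing AlignedPair (avoids re-aligning)
smut_from_alignment <- function(ap) {
  gl <- strsplit(ap$glAligned, "", fixed = TRUE)[[1]]
  lc <- strsplit(ap$lcAligned, "", fixed = TRUE)[[1]]
  ins <- gl == "-"
  if (any(ins))
    stop("light chain covers positions the germline lacks (insertion at ",
         "alignment column ", which(ins)[1], "); numbering inconsistency",
         call. = FALSE)
  tok <- ifelse(lc == "-", MISSING_TOKEN, ifelse(lc == gl, X_TOKEN, lc))
  list(tokens = tok, string = paste(tok, collapse = ""),
       nSM = sum(tok %in% AA_CODES))
}

#' Reconstruct a light chain from its encoding
#'
#' Inverse of the encoding over covered positions: `"X"` takes the germline
#' residue, an amino-acid token takes itself, `"."` yields `NA`.
#'
#' @param tokensVec character token vector over germline positions.
#' @param glSeq the germline sequence (same positions).
#' @return character vector of residues with `NA` at uncovered positions.
#' @export
decodeSMut <- function(tokensVec, glSeq) {
  gl <- strsplit(glSeq, "", fixed = TRUE)[[1]]
  if (length(gl) != length(tokensVec))
    stop("token vector and germline have different lengths", call. = FALSE)
  ifelse(tokensVec == MISSING_TOKEN, NA_character_,
         ifelse(tokensVec == X_TOKEN, gl, tokensVec))
}

## Map a single record onto the scheme universe. `posOf` maps kc label to
## scheme position. Returns a full-length token vector.
encode_one <- function(seq, gl, glLabVec, posOf, id = "sequence") {
  ap <- globalAlign(seq, gl)
  lcLabels <- transferNumbering(ap, glLabVec)
  extra <- setdiff(lcLabels, names(posOf))
  if (length(extra))
    stop(sprintf("%s: label(s) %s outside the scheme universe", id,
                 paste(extra, collapse = ", ")), call. = FALSE)
  bad <- setdiff(lcLabels, glLabVec)
  if (length(bad))
    stop(sprintf(
      "%s: covers position(s) %s that its germline lacks (numbering inconsistency)",
      id, paste(bad, collapse = ", ")), call. = FALSE)
  enc <- smutEncoding(seq, gl)
  tok <- rep(MISSING_TOKEN, length(posOf))
  tok[posOf[glLabVec]] <- enc$tokens
  tok
}

#' Encode a labeled dataset as a [SMutExperiment-class]
#'
#' Runs the full numbering pipeline on every record: global alignment to its
#' germline, Kabat-Chothia label transfer, progressive renumbering over the
#' joint label universe (all germline references plus any dataset insertions),
#' and per-position somatic-mutation token assignment. Positions a sequence
#' does not cover (e.g. a germline it does not use, or a truncated read) are
#' `"."`.
#'
#' @param records data.frame with columns `sequence_id`, `sequence`,
#'   `germline_id`, `label` (tox/nox/unknown), as returned by [readDataset()]
#'   or [generateRepertoire()].
#' @param germlines a [GermlineSet-class] resolving every `germline_id`.
#' @return a [SMutExperiment-class] (positions x sequences).
#' @export
encodeDataset <- function(records, germlines) {
  stopifnot(is.data.frame(records),
            all(c("sequence_id", "sequence", "germline_id", "label") %in%
                  names(records)))
  if (anyDuplicated(records$sequence_id))
    stop("duplicate sequence_id in dataset", call. = FALSE)
  missing_gl <- setdiff(records$germline_id, germlineIds(germlines))
  if (length(missing_gl))
    stop("unresolved germline id(s): ", paste(missing_gl, collapse = ", "),
         call. = FALSE)
  al_log("INFO", "encoding ", nrow(records), " sequences")

  ## Pass 1: align + transfer labels, collecting the label universe.
  aligned <- vector("list", nrow(records))
  lc_labels <- vector("list", nrow(records))
  labels_seen <- lapply(germlineIds(germlines),
                        function(id) glLabels(germlines, id))
  for (k in seq_len(nrow(records))) {
    gid <- records$germline_id[k]
    ap <- globalAlign(records$sequence[k], glSequence(germlines, gid))
    aligned[[k]] <- ap
    lc_labels[[k]] <- transferNumbering(ap, glLabels(germlines, gid))
  }
  posOf <- renumberProgressive(unique(unlist(c(labels_seen, lc_labels))))
  N <- length(posOf)

  tok <- matrix(MISSING_TOKEN, nrow = N, ncol = nrow(records),
                dimnames = list(NULL, records$sequence_id))
  for (k in seq_len(nrow(records))) {
    gid <- records$germline_id[k]
    glLabVec <- glLabels(germlines, gid)
    bad <- setdiff(lc_labels[[k]], glLabVec)
    if (length(bad))
      stop(sprintf(
        "%s: covers position(s) %s that its germline lacks (numbering inconsistency)",
        records$sequence_id[k], paste(bad, collapse = ", ")), call. = FALSE)
    enc <- smut_from_alignment(aligned[[k]])
    tok[posOf[glLabVec], k] <- enc$tokens
  }

  se <- SummarizedExperiment(
    assays = list(tokens = tok),
    rowData = DataFrame(position = seq_len(N), kc_label = names(posOf)),
    colData = DataFrame(label = records$label,
                        germline_id = records$germline_id,
                        n_sm = colSums(matrix(tok %in% AA_CODES, nrow = N)),
                        row.names = records$sequence_id))
  new("SMutExperiment", se)
}

#' Encode one sequence against an existing scheme universe
#'
#' Used at prediction/reversion time: the new sequence must fit inside the
#' universe the model was trained on.
#'
#' @param seq amino-acid string.
#' @param germlineId id resolved against `germlines`.
#' @param germlines a [GermlineSet-class].
#' @param universe data.frame with `position` and `kc_label`
#'   (see [positionUniverse()]).
#' @return character token vector of length `nrow(universe)`.
#' @export
encodeSequenceTokens <- function(seq, germlineId, germlines, universe) {
  posOf <- setNames(as.integer(universe$position), universe$kc_label)
  encode_one(seq, glSequence(germlines, germlineId),
             glLabels(germlines, germlineId), posOf)
}
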