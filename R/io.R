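# Readers/writers for the on-disk artifacts: FASTA sequences, TSV labels and
# germline sidecars, contact-map JSON, report tables, YAML config.

#' Read an amino-acid FASTA file
#'
#' Wraps [Biostrings::readAAStringSet] with validation: sequences are
#' upper-cased, and any character outside the 20 standard one-letter codes
#' (including gap characters) is rejected with the record index and position.
#'
#' @param path FASTA file.
#' @return named character vector of sequences (order preserved).
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e)
                    stop("FASTA parse error in ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  for (k in seq_along(seqs)) {
    if (!nzchar(ids[k]))
      stop(sprintf("record %d: empty FASTA header", k), call. = FALSE)
    if (!nzchar(seqs[k]))
      stop(sprintf("record %d ('%s'): empty sequence", k, ids[k]),
           call. = FALSE)
    check_aa(seqs[k], sprintf("record %d ('%s')", k, ids[k]))
  }
  setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of amino-acid sequences.
#' @param path output file.
#' @export
writeFasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path, width = 60L)
  invisible(path)
}

#' Read a germline reference: FASTA plus Kabat-Chothia sidecar
#'
#' The sidecar is a 3-column tab-separated table `germline_id`,
#' `residue_index` (1-based) and `kc_label`, one row per germline residue.
#'
#' @param fastaPath germline FASTA.
#' @param labelsPath sidecar TSV.
#' @return a [GermlineSet-class].
#' @export
readGermlineSet <- function(fastaPath, labelsPath) {
  seqs <- readFasta(fastaPath)
  tab <- read.delim(labelsPath, header = TRUE, sep = "\t",
                    colClasses = "character")
  need <- c("germline_id", "residue_index", "kc_label")
  if (!all(need %in% names(tab)))
    stop("germline sidecar must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  dangling <- setdiff(unique(tab$germline_id), names(seqs))
  if (length(dangling))
    stop("sidecar references unknown germline(s): ",
         paste(dangling, collapse = ", "), call. = FALSE)
  labs <- lapply(names(seqs), function(id) {
    rows <- tab[tab$germline_id == id, , drop = FALSE]
    if (!nrow(rows)) stop("no labels for germline ", id, call. = FALSE)
    rows <- rows[order(as.integer(rows$residue_index)), , drop = FALSE]
    if (!identical(as.integer(rows$residue_index),
                   seq_len(nchar(seqs[[id]]))))
      stop("label rows for ", id, " do not cover residues 1..",
           nchar(seqs[[id]]), call. = FALSE)
    rows$kc_label
  })
  GermlineSet(names(seqs), unname(seqs), labs)
}

#' Read a labeled light-chain dataset
#'
#' Joins a FASTA of light chains with a 2-column tab-separated label table
#' (`sequence_id`, `label` in tox/nox/unknown) and validates germline ids
#' against a reference. The join is order-independent: record order follows
#' the FASTA.
#'
#' @param fastaPath light-chain FASTA.
#' @param labelsPath label TSV; an optional third column `germline_id`
#'   assigns germlines per sequence, otherwise `germlineId` applies to all.
#' @param germlines a [GermlineSet-class].
#' @param germlineId default germline id when the label table carries none.
#' @return data.frame with `sequence_id`, `sequence`, `germline_id`, `label`.
#' @export
readDataset <- function(fastaPath, labelsPath, germlines, germlineId = NULL) {
  seqs <- readFasta(fastaPath)
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence ids in FASTA", call. = FALSE)
  tab <- read.delim(labelsPath, header = TRUE, sep = "\t",
                    colClasses = "character")
  if (!all(c("sequence_id", "label") %in% names(tab)))
    stop("label table must have columns sequence_id, label", call. = FALSE)
  dangling <- setdiff(tab$sequence_id, names(seqs))
  if (length(dangling))
    stop("label row(s) for id(s) absent from FASTA: ",
         paste(dangling, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(tab$label), c("tox", "nox", "unknown"))
  if (length(bad))
    stop("unknown label token(s): ", paste(bad, collapse = ", "),
         " (expected tox, nox or unknown)", call. = FALSE)
  lab <- setNames(tab$label, tab$sequence_id)
  unlabeled <- setdiff(names(seqs), tab$sequence_id)
  if (length(unlabeled))
    stop("sequence(s) without a label row: ",
         paste(unlabeled, collapse = ", "), call. = FALSE)
  if ("germline_id" %in% names(tab)) {
    gid <- setNames(tab$germline_id, tab$sequence_id)[names(seqs)]
  } else {
    if (is.null(germlineId))
      stop("no germline_id column and no default germlineId given",
           call. = FALSE)
    gid <- rep(germlineId, length(seqs))
  }
  missing_gl <- setdiff(unique(gid), germlineIds(germlines))
  if (length(missing_gl))
    stop("unresolved germline id(s): ", paste(missing_gl, collapse = ", "),
         call. = FALSE)
  data.frame(sequence_id = names(seqs), sequence = unname(seqs),
             germline_id = unname(gid), label = unname(lab[names(seqs)]),
             stringsAsFactors = FALSE)
}

#' Write / read an experiment-grid report table
#'
#' One row per experiment configuration with all six performance metrics, in
#' a deterministic column order.
#'
#' @param report data.frame as returned by [runGrid()]`$results`.
#' @param path output TSV.
#' @export
writeReport <- function(report, path) {
  cols <- c("families", "algorithm", "smote", "auc", "sensitivity",
            "specificity", "accuracy", "balanced_accuracy", "f1")
  stopifnot(all(cols %in% names(report)))
  write.table(report[, cols, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeReport
#' @export
readReport <- function(path) {
  out <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  out$smote <- as.logical(out$smote)
  out
}

#' Contact-map JSON cache
#'
#' Schema: `{structure_id, threshold, chain_pair, monomeric: [[i,j],...],
#' dimeric: [[i,j],...]}`, so the PDB file is needed only once.
#'
#' @param map a [ContactMap-class].
#' @param path JSON file.
#' @export
writeContactMap <- function(map, path) {
  obj <- list(structure_id = map@structureId,
              threshold = map@threshold,
              chain_pair = map@chainPair,
              monomeric = unname(split(map@monomeric, row(map@monomeric))),
              dimeric = unname(split(map@dimeric, row(map@dimeric))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeContactMap
#' @export
readContactMap <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_pairs <- function(x) {
    if (length(x) == 0) return(matrix(integer(0), 0, 2))
    m <- if (is.matrix(x)) x else do.call(rbind, x)
    storage.mode(m) <- "integer"
    m
  }
  new("ContactMap", monomeric = as_pairs(obj$monomeric),
      dimeric = as_pairs(obj$dimeric),
      threshold = as.numeric(obj$threshold),
      structureId = as.character(obj$structure_id),
      chainPair = as.character(obj$chain_pair))
}

#' Read a key-value configuration file
#'
#' YAML key-value config recognized keys: `contact_threshold` (default 7.5),
#' `info_gain_cutoff` (0.01), `folds` (10), `smote` (FALSE), `algorithm`
#' ("random_forest"), `seed` (1).
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return named list of settings.
#' @export
readConfig <- function(path = NULL) {
  defaults <- list(contact_threshold = 7.5, info_gain_cutoff = 0.01,
                   folds = 10L, smote = FALSE,
                   algorithm = "random_forest", seed = 1L)
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  utils::modifyList(defaults, user[names(user) %in% names(defaults)])
}
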