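# Structure-derived residue contacts: C-beta coordinates from a homodimeric
# light-chain structure, and the strict <7.5 A contact rule.

#' Extract per-residue C-beta coordinates from a PDB structure
#'
#' One coordinate per residue and chain: the C-beta atom, or the C-alpha as
#' surrogate where no C-beta exists (glycine). Alternate locations are
#' resolved by highest occupancy, then alphabetical altloc code.
#'
#' @param pdbPath PDB file (ATOM records).
#' @param chainIds character vector of chain identifiers to extract.
#' @return named list (per chain) of numeric matrices, rows named by PDB
#'   residue number, columns x/y/z.
#' @export
loadStructureCbeta <- function(pdbPath, chainIds) {
  ## keep all alternate locations: the occupancy rule below resolves them
  pdb <- bio3d::read.pdb(pdbPath, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  missing_ch <- setdiff(chainIds, unique(at$chain))
  if (length(missing_ch))
    stop("chain(s) not found in structure: ",
         paste(missing_ch, collapse = ", "), call. = FALSE)
  out <- list()
  for (ch in chainIds) {
    rows <- at[at$chain == ch, , drop = FALSE]
    resnos <- unique(rows$resno)
    coords <- matrix(NA_real_, length(resnos), 3,
                     dimnames = list(as.character(resnos), c("x", "y", "z")))
    for (k in seq_along(resnos)) {
      res <- rows[rows$resno == resnos[k], , drop = FALSE]
      cand <- res[res$elety == "CB", , drop = FALSE]
      if (!nrow(cand)) cand <- res[res$elety == "CA", , drop = FALSE]
      if (!nrow(cand))
        stop(sprintf("chain %s residue %d has neither CB nor CA", ch,
                     resnos[k]), call. = FALSE)
      if (nrow(cand) > 1) {
        occ <- cand$o
        occ[is.na(occ)] <- 0
        alt <- cand$alt
        alt[is.na(alt)] <- ""
        cand <- cand[order(-occ, alt), , drop = FALSE]
      }
      coords[k, ] <- as.numeric(cand[1, c("x", "y", "z")])
    }
    out[[ch]] <- coords
  }
  out
}

## All unordered pairs of rownames(a) x rownames(b) with euclidean distance
## strictly below thr; within = TRUE drops self pairs and the duplicate
## orientation.
pairs_below <- function(a, b, thr, within) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * (a %*% t(b))
  hit <- which(d2 < thr^2, arr.ind = TRUE)
  if (within) hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
  cbind(as.integer(rownames(a)[hit[, 1]]), as.integer(rownames(b)[hit[, 2]]))
}

#' Build a contact map from two chains' C-beta coordinates
#'
#' Monomeric pairs are within-chain contacts (union over the two chains);
#' dimeric pairs cross the chains and may pair a position with itself, which
#' the 2-fold symmetry of a homodimer makes natural. The cutoff is a strict
#' inequality: residues exactly at the threshold are not in contact. No
#' sequence-separation filter is applied within chains.
#'
#' @param coordsChain1,coordsChain2 residue-by-xyz matrices from
#'   [loadStructureCbeta()], rows named by PDB residue number.
#' @param pdbToScheme data.frame with columns `chain`, `resnum`,
#'   `scheme_position` mapping every PDB residue used to a scheme position.
#' @param threshold contact cutoff in angstroms.
#' @param structureId,chainIds identifiers stored in the result.
#' @return a [ContactMap-class] with pairs in scheme positions.
#' @export
buildContactMap <- function(coordsChain1, coordsChain2, pdbToScheme,
                            threshold = 7.5,
                            structureId = "structure",
                            chainIds = c("A", "B")) {
  stopifnot(all(c("chain", "resnum", "scheme_position") %in%
                  names(pdbToScheme)))
  to_scheme <- function(resnums, chain) {
    key <- paste(chain, resnums)
    lut <- setNames(pdbToScheme$scheme_position,
                    paste(pdbToScheme$chain, pdbToScheme$resnum))
    hit <- lut[key]
    if (anyNA(hit))
      stop("unmapped PDB residue(s): ",
           paste(key[is.na(hit)], collapse = ", "), call. = FALSE)
    as.integer(hit)
  }
  canon <- function(m) {
    if (!nrow(m)) return(matrix(integer(0), 0, 2))
    m <- cbind(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
    m <- unique(m)
    m[order(m[, 1], m[, 2]), , drop = FALSE]
  }
  mono <- rbind(pairs_below(coordsChain1, coordsChain1, threshold, TRUE),
                pairs_below(coordsChain2, coordsChain2, threshold, TRUE))
  if (nrow(mono)) {
    half <- nrow(pairs_below(coordsChain1, coordsChain1, threshold, TRUE))
    ch <- rep(chainIds, c(half, nrow(mono) - half))
    mono <- cbind(to_scheme(mono[, 1], ch), to_scheme(mono[, 2], ch))
  }
  dim_raw <- pairs_below(coordsChain1, coordsChain2, threshold, FALSE)
  if (nrow(dim_raw)) {
    dim_raw <- cbind(to_scheme(dim_raw[, 1], chainIds[1]),
                     to_scheme(dim_raw[, 2], chainIds[2]))
  }
  mono <- canon(mono)
  mono <- mono[mono[, 1] != mono[, 2], , drop = FALSE]
  new("ContactMap", monomeric = canon(mono), dimeric = canon(dim_raw),
      threshold = threshold, structureId = structureId,
      chainPair = chainIds)
}
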