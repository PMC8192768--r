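# Synthetic repertoire generator: labeled light-chain datasets with known
# planted ground truth, plus a toy homodimer structure, so the whole
# pipeline is testable offline.

## n Kabat-Chothia labels with `nIns` insertion letters after `insertAfter`
## (e.g. 1..30, 30A, 30B, 31..): the toy analogue of CDR insertion blocks.
make_kc_labels <- function(n, insertAfter = NA, nIns = 0L) {
  if (is.na(insertAfter) || nIns == 0L) return(as.character(seq_len(n)))
  stopifnot(insertAfter + nIns <= n)
  c(as.character(seq_len(insertAfter)),
    paste0(insertAfter, LETTERS[seq_len(nIns)]),
    as.character(seq(insertAfter + 1L, length.out = n - insertAfter - nIns)))
}

#' Bundled toy germline reference set
#'
#' Four hand-written, clearly synthetic lambda-like germline V-J sequences
#' (~105-112 residues) with Kabat-Chothia labels, two of them carrying
#' insertion-letter blocks so the progressive renumbering is exercised. They
#' mimic the shape of a real germline reference — framework/CDR architecture
#' and insertion codes — not its actual sequence content.
#'
#' @return a [GermlineSet-class].
#' @export
toyGermlineSet <- function() {
  seqs <- c(
    "SYNV1*01:SYNJ1*01" = paste0(
      "QSVLTQPPSVSGAPGQRVTISCTGSSSNIGAGYDVHWYQQLPGTAPKLLIYGNSNRPSGV",
      "PDRFSGSKSGTSASLAITGLQAEDEADYYCQSYDSSLSGSVFGGGTKLTVL"),
    "SYNV2*01:SYNJ2*01" = paste0(
      "QSALTQPASVSGSPGQSITISCTGTSSDVGGYNYVSWYQQHPGKAPKLMIYDVSNRPSGV",
      "SNRFSGSKSGNTASLTISGLQAEDEADYYCSSYTSSSTLVFGGGTKVTVL"),
    "SYNV3*01:SYNJ1*01" = paste0(
      "SYELTQPPSVSVSPGQTASITCSGDKLGDKYACWYQQKPGQSPVLVIYQDSKRPSGIPE",
      "RFSGSNSGNTATLTISGTQAMDEADYYCQAWDSSTVVFGGGTKLTVL"),
    "SYNV1*44:SYNJ3*01" = paste0(
      "QPVLTQPPSASGTPGQRVTISCSGSSSNIGSNTVNWYQQLPGTAPKLLIYSNNQRPSGV",
      "PDRFSGSKSGTSASLAISGLQSEDEADYYCAAWDDSLNGWVFGGGTKLTVL"))
  labs <- list(
    make_kc_labels(nchar(seqs[[1]]), insertAfter = 30, nIns = 3),
    make_kc_labels(nchar(seqs[[2]])),
    make_kc_labels(nchar(seqs[[3]]), insertAfter = 95, nIns = 1),
    make_kc_labels(nchar(seqs[[4]])))
  GermlineSet(names(seqs), unname(seqs), labs)
}

#' Simulation specification
#'
#' Defines a synthetic repertoire: class sizes, a uniform per-position
#' background somatic-mutation rate, planted single-position effects
#' (a specific residue appearing with different probabilities in the two
#' classes), planted contact-pair effects, class-conditional germline usage
#' and a seed. Generation is a pure function of the spec.
#'
#' @param germlines a [GermlineSet-class] (default [toyGermlineSet()]).
#' @param nTox,nNox class sizes.
#' @param backgroundRate per-position probability of a background somatic
#'   mutation (uniform over the 19 non-germline residues). Default 0.03, a
#'   typical per-residue replacement load for a moderately mutated light
#'   chain.
#' @param plantedEffects data.frame `position` (scheme), `aa`, `p_tox`,
#'   `p_nox`, or `NULL`.
#' @param pairEffects data.frame `pos1`, `pos2`, `aa1`, `aa2`, `p_tox`,
#'   `p_nox`, or `NULL`.
#' @param usage optional matrix (rows `tox`, `nox`) of per-germline usage
#'   probabilities; default uniform.
#' @param seed integer.
#' @return a `SimSpec` list.
#' @export
simSpec <- function(germlines = toyGermlineSet(), nTox = 100L, nNox = 150L,
                    backgroundRate = 0.03, plantedEffects = NULL,
                    pairEffects = NULL, usage = NULL, seed = 1L) {
  ids <- germlineIds(germlines)
  if (is.null(usage)) {
    usage <- matrix(1 / length(ids), 2, length(ids),
                    dimnames = list(c("tox", "nox"), ids))
  }
  spec <- structure(list(germlines = germlines, nTox = as.integer(nTox),
                         nNox = as.integer(nNox),
                         backgroundRate = backgroundRate,
                         plantedEffects = plantedEffects,
                         pairEffects = pairEffects, usage = usage,
                         seed = as.integer(seed)),
                    class = "SimSpec")
  validate_simspec(spec)
  spec
}

## scheme position of each residue, per germline
scheme_positions <- function(germlines) {
  ids <- germlineIds(germlines)
  all_labs <- unique(unlist(lapply(ids, function(id)
    glLabels(germlines, id))))
  posOf <- renumberProgressive(all_labs)
  list(posOf = posOf,
       perGl = setNames(lapply(ids, function(id)
         unname(posOf[glLabels(germlines, id)])), ids))
}

validate_simspec <- function(spec) {
  probs <- c(spec$backgroundRate, spec$usage,
             spec$plantedEffects$p_tox, spec$plantedEffects$p_nox,
             spec$pairEffects$p_tox, spec$pairEffects$p_nox)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  sp <- scheme_positions(spec$germlines)
  N <- length(sp$posOf)
  eff_pos <- c(spec$plantedEffects$position, spec$pairEffects$pos1,
               spec$pairEffects$pos2)
  if (length(eff_pos) && any(eff_pos < 1 | eff_pos > N))
    stop("planted position outside the scheme universe (1..", N, ")",
         call. = FALSE)
  pe <- spec$plantedEffects
  if (!is.null(pe)) {
    for (i in seq_len(nrow(pe))) {
      for (id in germlineIds(spec$germlines)) {
        idx <- match(pe$position[i], sp$perGl[[id]])
        if (!is.na(idx) &&
            substr(glSequence(spec$germlines, id), idx, idx) == pe$aa[i])
          stop(sprintf(
            "contradictory spec: planted residue %s at position %d equals the %s germline residue",
            pe$aa[i], pe$position[i], id), call. = FALSE)
      }
    }
  }
  invisible(spec)
}

#' Generate a labeled synthetic repertoire
#'
#' For each sequence: draw a germline by class-conditional usage, apply
#' background somatic mutations (uniform substitution to a non-germline
#' residue), then apply planted single-position and pair effects with their
#' class-conditional probabilities (planted residues overwrite background
#' ones). No indels are introduced, mirroring the substitution-only nature
#' of the somatic-mutation encoding.
#'
#' @param spec a [simSpec()] object.
#' @return list: `records` (data.frame `sequence_id`, `sequence`,
#'   `germline_id`, `label`), `truth` (the planted effects with realized
#'   per-class carrier counts), and `germlines`.
#' @export
generateRepertoire <- function(spec) {
  stopifnot(inherits(spec, "SimSpec"))
  sp <- scheme_positions(spec$germlines)
  ids <- germlineIds(spec$germlines)
  glchars <- lapply(ids, function(id)
    strsplit(glSequence(spec$germlines, id), "", fixed = TRUE)[[1]])
  names(glchars) <- ids

  pe <- spec$plantedEffects
  qe <- spec$pairEffects
  pe_hits <- if (is.null(pe)) NULL else matrix(0L, nrow(pe), 2,
                                               dimnames = list(NULL, c("tox", "nox")))
  qe_hits <- if (is.null(qe)) NULL else matrix(0L, nrow(qe), 2,
                                               dimnames = list(NULL, c("tox", "nox")))

  gen_class <- function(class, n) {
    recs <- vector("list", n)
    for (k in seq_len(n)) {
      gid <- if (length(ids) == 1) ids else
        sample(ids, 1, prob = spec$usage[class, ids])
      res <- glchars[[gid]]
      pos <- sp$perGl[[gid]]
      mut <- which(runif(length(res)) < spec$backgroundRate)
      for (i in mut)
        res[i] <- sample(setdiff(AA_CODES, res[i]), 1)
      if (!is.null(pe)) {
        for (e in seq_len(nrow(pe))) {
          idx <- match(pe$position[e], pos)
          if (!is.na(idx) && runif(1) < pe[[paste0("p_", class)]][e]) {
            res[idx] <- pe$aa[e]
            pe_hits[e, class] <<- pe_hits[e, class] + 1L
          }
        }
      }
      if (!is.null(qe)) {
        for (e in seq_len(nrow(qe))) {
          i1 <- match(qe$pos1[e], pos); i2 <- match(qe$pos2[e], pos)
          if (!is.na(i1) && !is.na(i2) &&
              runif(1) < qe[[paste0("p_", class)]][e]) {
            res[i1] <- qe$aa1[e]; res[i2] <- qe$aa2[e]
            qe_hits[e, class] <<- qe_hits[e, class] + 1L
          }
        }
      }
      recs[[k]] <- data.frame(
        sequence_id = sprintf("%s%05d", class, k),
        sequence = paste(res, collapse = ""),
        germline_id = gid, label = class, stringsAsFactors = FALSE)
    }
    recs
  }

  empty <- data.frame(sequence_id = character(0), sequence = character(0),
                      germline_id = character(0), label = character(0),
                      stringsAsFactors = FALSE)
  records <- with_seed(spec$seed,
    do.call(rbind, c(list(empty), gen_class("tox", spec$nTox),
                     gen_class("nox", spec$nNox))))
  truth <- list()
  if (!is.null(pe)) truth$planted <- cbind(pe, n_tox = pe_hits[, "tox"],
                                           n_nox = pe_hits[, "nox"])
  if (!is.null(qe)) truth$pairs <- cbind(qe, n_tox = qe_hits[, "tox"],
                                         n_nox = qe_hits[, "nox"])
  list(records = records, truth = truth, germlines = spec$germlines)
}

#' Generate a toy homodimer structure with designed contacts
#'
#' Writes a two-chain PDB (CA and CB atoms, alanines) whose geometry
#' realizes a requested contact pattern: designated interface positions sit
#' 5 A apart across the chains, designated monomeric neighbour pairs sit
#' 5-7.1 A apart within each chain, and every other pair is farther than
#' 9 A. Residue numbers equal scheme positions; a chain/resnum-to-scheme map
#' is returned alongside.
#'
#' Constraints (violations raise a geometric-infeasibility error): a
#' position may belong to at most one monomeric pair, and the two members of
#' a monomeric pair may not both be interface positions.
#'
#' @param positions integer vector of scheme positions (>= 2).
#' @param interfacePositions subset forming cross-chain contacts.
#' @param monomericPairs optional 2-column matrix of within-chain contact
#'   pairs.
#' @return list: `pdb` (character vector of PDB lines), `map` (data.frame
#'   `chain`, `resnum`, `scheme_position`).
#' @export
generateToyStructure <- function(positions, interfacePositions = integer(0),
                                 monomericPairs = NULL) {
  positions <- sort(unique(as.integer(positions)))
  if (length(positions) < 2) stop("need at least 2 positions", call. = FALSE)
  if (length(setdiff(interfacePositions, positions)))
    stop("interface positions must be a subset of positions", call. = FALSE)
  if (is.null(monomericPairs))
    monomericPairs <- matrix(integer(0), 0, 2)
  if (nrow(monomericPairs)) {
    mem <- as.vector(monomericPairs)
    if (length(setdiff(mem, positions)) || anyDuplicated(mem))
      stop("geometric infeasibility: monomeric pairs must be disjoint and ",
           "within positions", call. = FALSE)
    both_if <- monomericPairs[, 1] %in% interfacePositions &
      monomericPairs[, 2] %in% interfacePositions
    if (any(both_if))
      stop("geometric infeasibility: both members of a monomeric pair are ",
           "interface positions", call. = FALSE)
  }

  partner_of <- setNames(monomericPairs[, 1], monomericPairs[, 2])
  x <- setNames(numeric(length(positions)), positions)
  slot <- 0
  for (p in positions) {
    if (as.character(p) %in% names(partner_of)) next
    x[as.character(p)] <- 20 * slot
    slot <- slot + 1
  }
  for (p2 in names(partner_of))
    x[p2] <- x[as.character(partner_of[[p2]])] + 5

  yA <- ifelse(positions %in% interfacePositions, 5, 0)
  yB <- ifelse(positions %in% interfacePositions, 10, 15)

  fmt <- "ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %s"
  lines <- character(0)
  serial <- 0L
  for (chain in c("A", "B")) {
    for (k in seq_along(positions)) {
      p <- positions[k]
      yy <- if (chain == "A") yA[k] else yB[k]
      serial <- serial + 1L
      lines <- c(lines, sprintf(fmt, serial, " CA", "ALA", chain, p,
                                x[as.character(p)], yy, 1.5, 1, 0, "C"))
      serial <- serial + 1L
      lines <- c(lines, sprintf(fmt, serial, " CB", "ALA", chain, p,
                                x[as.character(p)], yy, 0, 1, 0, "C"))
    }
    lines <- c(lines, "TER")
  }
  lines <- c(lines, "END")
  map <- data.frame(chain = rep(c("A", "B"), each = length(positions)),
                    resnum = rep(positions, 2),
                    scheme_position = rep(positions, 2))
  list(pdb = lines, map = map)
}
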