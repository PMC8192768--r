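# Germline alignment, Kabat-Chothia label transfer and progressive renumbering.

## Total order on Kabat-Chothia labels: numeric part first, then insertion
## letter with the bare label ("30") before its insertions ("30A" < "30B").
## Returns a numeric rank usable for sorting/comparison.
kabat_rank <- function(labels) {
  num <- as.integer(sub("([0-9]+)[A-Z]?$", "\\1", labels))
  letter <- sub("^[0-9]+", "", labels)
  if (any(is.na(num)) || any(!letter %in% c("", LETTERS)))
    stop("malformed Kabat-Chothia label(s): ",
         paste(labels[is.na(num) | !letter %in% c("", LETTERS)], collapse = ", "),
         call. = FALSE)
  num * 27 + match(letter, c("", LETTERS)) - 1L
}

#' Sort Kabat-Chothia labels
#'
#' Orders labels by numeric part then insertion letter, the ordering that the
#' progressive renumbering preserves ("30" < "30A" < "30B" < "31").
#'
#' @param labels character vector of labels such as `"30"`, `"30A"`.
#' @return the labels in Kabat order.
#' @export
kabatSort <- function(labels) labels[order(kabat_rank(labels))]

#' Optimal global alignment of a light chain to its germline
#'
#' Needleman-Wunsch global alignment with linear gap costs. Because a mature
#' light chain differs from its own germline only by somatic mutations and the
#' occasional junction indel, these alignments are near-identity; the scoring
#' defaults (match +1, mismatch -1, gap -4) are deliberately simple and
#' configurable. The stiff gap penalty keeps point substitutions inside
#' short sequence repeats from being misread as micro-indels, which would
#' shift the numbering. Traceback is deterministic: on score ties a
#' match/mismatch column is preferred, then a gap in the light chain, then a
#' gap in the germline.
#'
#' @param lcSeq,glSeq amino-acid strings (light chain, germline).
#' @param match,mismatch,gap scoring parameters (linear gap penalty).
#' @return list with `lcAligned`, `glAligned` (equal-length strings using
#'   `"-"` for gaps) and `score`.
#' @examples
#' globalAlign("SYELTQPP", "SYVLTQPP")
#' @export
globalAlign <- function(lcSeq, glSeq, match = 1, mismatch = -1, gap = -4) {
  if (!nzchar(lcSeq) || !nzchar(glSeq))
    stop("sequences must be non-empty", call. = FALSE)
  a <- strsplit(lcSeq, "", fixed = TRUE)[[1]]
  b <- strsplit(glSeq, "", fixed = TRUE)[[1]]
  n1 <- length(a); n2 <- length(b)

  ## F[i+1, j+1] = best score aligning a[1..i] with b[1..j]. The row is filled
  ## with a running-max trick so the horizontal (gap-in-LC) recurrence
  ## vectorizes: x_j = gap*j + cummax(c(x_0, V_j - gap*j)).
  F <- matrix(0, n1 + 1L, n2 + 1L)
  F[1L, ] <- gap * (0:n2)
  F[, 1L] <- gap * (0:n1)
  j_idx <- seq_len(n2)
  gj <- gap * j_idx
  for (i in seq_len(n1)) {
    s <- mismatch + (b == a[i]) * (match - mismatch)
    prev <- F[i, ]
    V <- pmax(prev[j_idx] + s, prev[j_idx + 1L] + gap)
    cm <- cummax(c(F[i + 1L, 1L], V - gj))
    F[i + 1L, j_idx + 1L] <- gj + cm[j_idx + 1L]
  }

  ## Traceback, tie order: diagonal, then left (gap in LC), then up.
  i <- n1; j <- n2
  la <- character(n1 + n2); ga <- character(n1 + n2)
  k <- n1 + n2 + 1L
  while (i > 0L || j > 0L) {
    k <- k - 1L
    if (i > 0L && j > 0L &&
        F[i + 1L, j + 1L] ==
          F[i, j] + (if (a[i] == b[j]) match else mismatch)) {
      la[k] <- a[i]; ga[k] <- b[j]; i <- i - 1L; j <- j - 1L
    } else if (j > 0L && F[i + 1L, j + 1L] == F[i + 1L, j] + gap) {
      la[k] <- "-"; ga[k] <- b[j]; j <- j - 1L
    } else {
      la[k] <- a[i]; ga[k] <- "-"; i <- i - 1L
    }
  }
  cols <- seq.int(k, n1 + n2)
  list(lcAligned = paste(la[cols], collapse = ""),
       glAligned = paste(ga[cols], collapse = ""),
       score = F[n1 + 1L, n2 + 1L])
}

## Next insertion label after `lab`: "30" -> "30A", "30A" -> "30B".
## An insertion before any germline residue hangs off the virtual label "0".
next_insertion <- function(lab) {
  if (is.null(lab)) lab <- "0"
  letter <- sub("^[0-9]+", "", lab)
  num <- sub("([0-9]+)[A-Z]?$", "\\1", lab)
  if (letter == "") return(paste0(lab, "A"))
  if (letter == "Z")
    stop("insertion letters exhausted past 'Z' after label ", num,
         call. = FALSE)
  paste0(num, LETTERS[match(letter, LETTERS) + 1L])
}

#' Transfer Kabat-Chothia labels through an alignment
#'
#' Light-chain residues aligned to a germline residue inherit its label;
#' residues in insertion columns (germline gap) get the preceding label with
#' the next insertion letter; germline-only columns yield no light-chain
#' label.
#'
#' @param aligned result of [globalAlign()].
#' @param glKcLabels Kabat-Chothia labels of the ungapped germline row.
#' @return character vector of labels, one per light-chain residue.
#' @export
transferNumbering <- function(aligned, glKcLabels) {
  gl <- strsplit(aligned$glAligned, "", fixed = TRUE)[[1]]
  lc <- strsplit(aligned$lcAligned, "", fixed = TRUE)[[1]]
  if (sum(gl != "-") != length(glKcLabels))
    stop("label count does not match the ungapped germline row", call. = FALSE)
  out <- character(sum(lc != "-"))
  gi <- 0L; li <- 0L; last <- NULL
  for (k in seq_along(gl)) {
    if (gl[k] != "-") {
      gi <- gi + 1L
      last <- glKcLabels[gi]
      if (lc[k] != "-") { li <- li + 1L; out[li] <- last }
    } else {
      li <- li + 1L
      last <- next_insertion(last)
      out[li] <- last
    }
  }
  out
}

#' Progressive renumbering of a Kabat-Chothia label universe
#'
#' Maps the sorted union of labels seen across a dataset and its germline
#' references onto contiguous integers 1..N, so that e.g. a CDR1 block
#' 30A..30F occupies 31..36 and every downstream position shifts accordingly.
#' The mapping is a strictly monotone bijection.
#'
#' @param labels character vector of Kabat-Chothia labels (no duplicates).
#' @return named integer vector mapping label to scheme position, in Kabat
#'   order.
#' @examples
#' renumberProgressive(c("29", "30", "30A", "30B", "31"))
#' @export
renumberProgressive <- function(labels) {
  if (anyDuplicated(labels))
    stop("duplicate label(s) in universe: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  setNames(seq_along(labels), kabatSort(labels))
}
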