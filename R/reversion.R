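# Germline reversion: rank a predicted-toxic sequence's somatic mutations by
# feature importance and restore germline residues one at a time until the
# predicted phenotype flips.

#' Rank somatic mutations as reversion candidates
#'
#' Each somatic mutation is scored by the best (smallest) general rank among
#' the ranked value-level features the sequence currently exhibits that
#' involve its position — its own (position, residue) feature and any
#' contact-pair feature containing the position with matching tokens.
#' Candidates are returned in ascending rank order, ties by position;
#' mutations touching no ranked feature come last.
#'
#' @param tokensVec token vector over the scheme universe.
#' @param ranked data.frame from [infoGainRank()].
#' @return data.frame: `position`, `residue`, `best_rank`, `driving_feature`
#'   (`NA` if none), ordered; zero rows if the sequence has no somatic
#'   mutations.
#' @export
rankSMCandidates <- function(tokensVec, ranked) {
  sm_pos <- which(tokensVec %in% AA_CODES)
  if (!length(sm_pos))
    return(data.frame(position = integer(0), residue = character(0),
                      best_rank = numeric(0), driving_feature = character(0),
                      stringsAsFactors = FALSE))
  score_one <- function(p) {
    hit_amp <- ranked$family == "AMP" & ranked$pos1 == p &
      ranked$level == tokensVec[p]
    hit_pair <- ranked$family %in% c("MAP", "DAP") &
      (ranked$pos1 == p | ranked$pos2 == p) &
      ranked$level == paste0(tokensVec[ranked$pos1], "-",
                             tokensVec[ranked$pos2])
    hits <- which(hit_amp | hit_pair)
    if (!length(hits)) return(list(rank = Inf, feature = NA_character_))
    best <- hits[which.min(ranked$general_rank[hits])]
    list(rank = ranked$general_rank[best], feature = ranked$name[best])
  }
  scored <- lapply(sm_pos, score_one)
  out <- data.frame(position = sm_pos,
                    residue = tokensVec[sm_pos],
                    best_rank = vapply(scored, `[[`, numeric(1), "rank"),
                    driving_feature = vapply(scored, `[[`, character(1),
                                             "feature"),
                    stringsAsFactors = FALSE)
  out[order(out$best_rank, out$position), , drop = FALSE]
}

#' Greedy germline reversion of a predicted-toxic sequence
#'
#' Encodes the sequence, then restores germline residues one somatic
#' mutation at a time in feature-rank order, re-encoding and re-predicting
#' after each step, until the prediction flips to non-toxic or the
#' candidates (or `maxSteps`) are exhausted. A sequence already predicted
#' non-toxic yields a no-op plan.
#'
#' @param seq amino-acid string of the light chain.
#' @param germlineId its germline id in `germlines`.
#' @param germlines a [GermlineSet-class].
#' @param model a `ToxModel` trained with a stored `universe`.
#' @param ranked data.frame from [infoGainRank()].
#' @param maxSteps cap on reversion steps.
#' @return a `ReversionPlan`: `sequence_id`-free list with `steps`
#'   (position, kc_label, from_aa, to_germline_aa, driving_feature,
#'   confidence_before, confidence_after), `final_label`,
#'   `final_confidence`, `final_sequence` and `exhausted` (TRUE if every
#'   candidate was reverted without flipping).
#' @export
greedyRevert <- function(seq, germlineId, germlines, model, ranked,
                         maxSteps = Inf) {
  if (is.null(model$universe))
    stop("model carries no scheme universe; retrain with universe=",
         call. = FALSE)
  uni <- model$universe
  tok <- encodeSequenceTokens(seq, germlineId, germlines, uni)
  glseq <- glSequence(germlines, germlineId)
  gllab <- glLabels(germlines, germlineId)
  gl_at <- setNames(strsplit(glseq, "", fixed = TRUE)[[1]],
                    as.character(uni$position[match(gllab, uni$kc_label)]))

  pred <- predictToxicity(model, tok, germlineIds = germlineId)
  plan <- list(steps = data.frame(), final_label = pred$label,
               final_confidence = pred$confidence,
               final_sequence = seq, exhausted = FALSE)
  class(plan) <- "ReversionPlan"
  if (pred$label == "nox") return(plan)

  cands <- rankSMCandidates(tok, ranked)
  steps <- list()
  conf <- pred$confidence
  n_done <- 0L
  for (k in seq_len(nrow(cands))) {
    if (n_done >= maxSteps) break
    p <- cands$position[k]
    from_aa <- cands$residue[k]
    to_aa <- gl_at[[as.character(p)]]
    tok[p] <- X_TOKEN
    n_done <- n_done + 1L
    pred <- predictToxicity(model, tok, germlineIds = germlineId)
    steps[[n_done]] <- data.frame(
      position = p, kc_label = uni$kc_label[uni$position == p],
      from_aa = from_aa, to_germline_aa = to_aa,
      driving_feature = cands$driving_feature[k],
      confidence_before = conf, confidence_after = pred$confidence,
      stringsAsFactors = FALSE)
    conf <- pred$confidence
    if (pred$label == "nox") break
  }
  plan$steps <- if (length(steps)) do.call(rbind, steps) else data.frame()
  plan$final_label <- pred$label
  plan$final_confidence <- pred$confidence
  plan$exhausted <- pred$label == "tox" && n_done == nrow(cands)
  ## apply the accepted steps to the input sequence: each step restores the
  ## germline residue at the residue index carrying that scheme position
  res <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (length(steps)) {
    ap <- globalAlign(seq, glseq)
    lcLabels <- transferNumbering(ap, gllab)
    lcPos <- uni$position[match(lcLabels, uni$kc_label)]
    st <- do.call(rbind, steps)
    for (i in seq_len(nrow(st)))
      res[which(lcPos == st$position[i])] <- st$to_germline_aa[i]
  }
  plan$final_sequence <- paste(res, collapse = "")
  plan
}

#' @export
print.ReversionPlan <- function(x, ...) {
  cat(sprintf("ReversionPlan: final label %s (confidence %.3f)%s\n",
              x$final_label, x$final_confidence,
              if (x$exhausted) " [all SMs reverted without flipping]" else ""))
  if (nrow(x$steps)) {
    for (i in seq_len(nrow(x$steps)))
      cat(sprintf("  step %d: %s%s%s (pos %d, feature %s)  %.3f -> %.3f\n",
                  i, x$steps$from_aa[i], x$steps$kc_label[i],
                  x$steps$to_germline_aa[i], x$steps$position[i],
                  x$steps$driving_feature[i],
                  x$steps$confidence_before[i], x$steps$confidence_after[i]))
  } else cat("  no steps\n")
  invisible(x)
}
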