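# Per-position mutation-enrichment statistics between tox and nox groups.

#' Per-position mutated / non-mutated counts
#'
#' For every scheme position, counts the toxic and non-toxic sequences with
#' and without a somatic mutation there. By default an uncovered position
#' (`"."`) counts as non-mutated — a truncated sequence is treated as
#' germline at positions it does not report; `missingAsNM = FALSE` instead
#' drops those sequences from that position's table.
#'
#' @param sme a [SMutExperiment-class] with tox/nox labels.
#' @param missingAsNM logical (see above).
#' @return data.frame: `position`, `kc_label`, `tox_M`, `tox_NM`, `nox_M`,
#'   `nox_NM`.
#' @export
countPositions <- function(sme, missingAsNM = TRUE) {
  lab <- toxLabels(sme)
  if (!any(lab == "tox") || !any(lab == "nox"))
    stop("both tox and nox sequences are required", call. = FALSE)
  tok <- tokens(sme)
  M <- matrix(tok %in% AA_CODES, nrow = nrow(tok))
  cov <- matrix(tok != MISSING_TOKEN, nrow = nrow(tok))
  cnt <- function(group) {
    sel <- lab == group
    m <- rowSums(M[, sel, drop = FALSE])
    nm <- if (missingAsNM) sum(sel) - m
          else rowSums(cov[, sel, drop = FALSE]) - m
    list(m = m, nm = nm)
  }
  tx <- cnt("tox"); nx <- cnt("nox")
  data.frame(position = rowData(sme)$position,
             kc_label = rowData(sme)$kc_label,
             tox_M = tx$m, tox_NM = tx$nm, nox_M = nx$m, nox_NM = nx$nm)
}

#' Sample odds ratio, confidence interval and Fisher exact p for a 2x2 table
#'
#' The odds ratio is the plain cross-product ratio
#' (tox_M / tox_NM) / (nox_M / nox_NM) — not the conditional MLE — reported
#' as `Inf`/`0`/`NaN` where cells are zero, with no continuity correction.
#' The 95% CI uses the Haldane-Anscombe +0.5 correction on the log odds so it
#' stays finite. The two-sided p-value is the exact test as implemented by
#' [stats::fisher.test] (sum of point probabilities not exceeding the
#' observed one).
#'
#' @param tox_M,tox_NM,nox_M,nox_NM the four counts.
#' @param conf confidence level for the interval.
#' @return list: `or`, `ci` (length 2), `p`.
#' @examples
#' fisherOR(54, 374, 8, 639)$or  # ~ 11.53
#' @export
fisherOR <- function(tox_M, tox_NM, nox_M, nox_NM, conf = 0.95) {
  tab <- matrix(c(tox_M, tox_NM, nox_M, nox_NM), 2)
  if (all(tab == 0)) stop("all-zero table", call. = FALSE)
  or <- (tox_M / tox_NM) / (nox_M / nox_NM)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  lse <- sqrt(sum(1 / (tab + 0.5)))
  lor <- log((tox_M + 0.5) * (nox_NM + 0.5) /
               ((tox_NM + 0.5) * (nox_M + 0.5)))
  ci <- exp(lor + c(-z, z) * lse)
  p <- stats::fisher.test(tab, conf.level = conf)$p.value
  list(or = or, ci = ci, p = p)
}

#' Per-position enrichment statistics table
#'
#' Combines [countPositions()] with [fisherOR()] at every position: the
#' per-position analogue of a mutation-enrichment scan between toxic and
#' non-toxic repertoires. No multiple-testing correction is applied by
#' default (each position is tested at its own alpha); `adjust = "BH"` adds
#' a Benjamini-Hochberg column `p_adj`.
#'
#' @inheritParams countPositions
#' @param adjust `"none"` or `"BH"`.
#' @return data.frame with counts, `odds_ratio`, `ci_low`, `ci_high`, `p`
#'   (and `p_adj` when requested).
#' @export
positionStats <- function(sme, missingAsNM = TRUE, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  cnt <- countPositions(sme, missingAsNM)
  res <- lapply(seq_len(nrow(cnt)), function(i)
    fisherOR(cnt$tox_M[i], cnt$tox_NM[i], cnt$nox_M[i], cnt$nox_NM[i]))
  cnt$odds_ratio <- vapply(res, function(r) r$or, numeric(1))
  cnt$ci_low <- vapply(res, function(r) r$ci[1], numeric(1))
  cnt$ci_high <- vapply(res, function(r) r$ci[2], numeric(1))
  cnt$p <- vapply(res, function(r) r$p, numeric(1))
  if (adjust == "BH") cnt$p_adj <- stats::p.adjust(cnt$p, "BH")
  cnt
}

#' Tri-partition positions by enrichment direction
#'
#' @param stats data.frame from [positionStats()].
#' @param alpha significance level.
#' @return list of position vectors: `enriched_in_tox` (p < alpha, OR > 1),
#'   `enriched_in_nox` (p < alpha, OR < 1), `nonsignificant` (everything
#'   else, including significant tables with OR exactly 1 or undefined).
#' @export
classifyPositions <- function(stats, alpha = 0.05) {
  sig <- !is.na(stats$p) & stats$p < alpha
  or <- stats$odds_ratio
  up <- sig & !is.na(or) & or > 1
  dn <- sig & !is.na(or) & or < 1
  list(enriched_in_tox = stats$position[up],
       enriched_in_nox = stats$position[dn],
       nonsignificant = stats$position[!(up | dn)])
}

#' Compare somatic-mutation count distributions between two groups
#'
#' Two-sided two-sample t-test (Welch) on per-sequence somatic-mutation
#' counts — the distribution-of-SM-count comparison used to check that two
#' repertoires carry similar mutation loads. If both groups are constant the
#' test is degenerate: equal means give p = 1 by convention, unequal means
#' p = 0.
#'
#' @param countsA,countsB integer vectors of per-sequence SM counts
#'   (each of length >= 2).
#' @return list with `t` and `p`.
#' @export
pdsmCompare <- function(countsA, countsB) {
  if (length(countsA) < 2 || length(countsB) < 2)
    stop("each group needs at least 2 sequences", call. = FALSE)
  if (stats::var(countsA) == 0 && stats::var(countsB) == 0) {
    if (mean(countsA) == mean(countsB)) return(list(t = 0, p = 1))
    return(list(t = sign(mean(countsA) - mean(countsB)) * Inf, p = 0))
  }
  tt <- stats::t.test(countsA, countsB)
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' Chance probability of a validation outcome
#'
#' Binomial point probability of exactly `nCorrect` correct calls out of
#' `nTotal` under coin-flip classification — the yardstick used to judge a
#' small hold-out validation against a random classifier.
#'
#' @param nCorrect,nTotal integers.
#' @param p success probability of the random classifier.
#' @return the point probability.
#' @examples
#' round(validationRandomProb(10, 12), 3)  # 0.016
#' @export
validationRandomProb <- function(nCorrect, nTotal, p = 0.5) {
  dbinom(nCorrect, nTotal, p)
}
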