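# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

## Best global-alignment score by exhaustive recursion over all alignments
## (no DP reuse beyond the call tree): exponential, for tiny strings only.
enum_align_score <- function(a, b, match = 1, mismatch = -1, gap = -4) {
  if (!nchar(a) && !nchar(b)) return(0)
  best <- -Inf
  if (nchar(a) && nchar(b)) {
    s <- if (substr(a, 1, 1) == substr(b, 1, 1)) match else mismatch
    best <- max(best, s + enum_align_score(substr(a, 2, nchar(a)),
                                           substr(b, 2, nchar(b)),
                                           match, mismatch, gap))
  }
  if (nchar(a))
    best <- max(best, gap + enum_align_score(substr(a, 2, nchar(a)), b,
                                             match, mismatch, gap))
  if (nchar(b))
    best <- max(best, gap + enum_align_score(a, substr(b, 2, nchar(b)),
                                             match, mismatch, gap))
  best
}

## Two-sided Fisher exact p by exhaustive hypergeometric enumeration over all
## tables with the observed margins (sum of point probabilities not exceeding
## the observed one, with R's relative-error guard).
enum_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(k, m)
  logp <- lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)
  p <- exp(logp)
  p_obs <- p[xs == a]
  sum(p[p <= p_obs * (1 + 1e-7)])
}

## All residue pairs of a coordinate set strictly below a distance threshold,
## by a plain double loop.
enum_contacts <- function(coordsA, coordsB, thr, within) {
  out <- NULL
  ra <- as.integer(rownames(coordsA)); rb <- as.integer(rownames(coordsB))
  for (i in seq_len(nrow(coordsA))) {
    for (j in seq_len(nrow(coordsB))) {
      if (within && ra[i] >= rb[j]) next
      if (sqrt(sum((coordsA[i, ] - coordsB[j, ])^2)) < thr) {
        pr <- sort(c(ra[i], rb[j]))
        out <- rbind(out, pr)
      }
    }
  }
  if (is.null(out)) return(matrix(integer(0), 0, 2))
  out <- unique(out)
  rownames(out) <- NULL
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

## Youden J by brute force over all unique cutpoints.
enum_youden_J <- function(scores, positive) {
  best <- -Inf
  for (c in unique(scores)) {
    se <- mean(scores[positive] >= c)
    sp <- mean(scores[!positive] < c)
    best <- max(best, se + sp - 1)
  }
  best
}

## A tiny two-germline reference for unit tests.
tiny_germlines <- function() {
  GermlineSet(c("GL1", "GL2"),
              c("SYVLTQPPSVSG", "QAVLTQPPPSAS"),
              list(as.character(1:12),
                   c(as.character(1:8), "8A", as.character(9:11))))
}

## A small planted-effect dataset shared by ML tests: one strongly
## discriminative position plus background noise.
planted_dataset <- function(n_tox = 60, n_nox = 80, seed = 42,
                            p_tox = 0.85, p_nox = 0.03) {
  spec <- simSpec(nTox = n_tox, nNox = n_nox, backgroundRate = 0.02,
                  plantedEffects = data.frame(position = 49, aa = "A",
                                              p_tox = p_tox, p_nox = p_nox),
                  seed = seed)
  sim <- generateRepertoire(spec)
  sme <- encodeDataset(sim$records, sim$germlines)
  list(sim = sim, sme = sme)
}
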