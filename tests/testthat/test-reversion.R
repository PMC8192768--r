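# Rank-guided germline reversion.

## A trained model + ranking on a strongly planted dataset, reused across
## tests; toxicity is driven by a single planted mutation at position 49.
revert_fixture <- function() {
  d <- planted_dataset(n_tox = 80, n_nox = 100, seed = 29, p_tox = 0.9,
                       p_nox = 0.02)
  fs <- assembleFeatureMatrix(d$sme, "AMP")
  model <- trainClassifier(fs, "random_forest", seed = 2,
                           universe = positionUniverse(d$sme))
  list(d = d, model = model, ranked = infoGainRank(fs),
       gl = d$sim$germlines)
}

## germline sequence carrying given (scheme position -> residue) edits
seq_with <- function(gl, gid, uni, edits) {
  posOf <- setNames(uni$position, uni$kc_label)
  res <- strsplit(glSequence(gl, gid), "")[[1]]
  pos_of_res <- posOf[glLabels(gl, gid)]
  for (p in names(edits)) res[which(pos_of_res == as.integer(p))] <- edits[[p]]
  paste(res, collapse = "")
}

test_that("candidate ranking orders somatic mutations by feature rank", {
  ranked <- data.frame(name = c("49-A", "60-E"), family = "AMP",
                       pos1 = c(49, 60), pos2 = NA, level = c("A", "E"),
                       general_rank = c(1, 2), stringsAsFactors = FALSE)
  tok <- rep("X", 80)
  expect_equal(nrow(rankSMCandidates(tok, ranked)), 0)

  tok[60] <- "E"; tok[49] <- "A"
  cand <- rankSMCandidates(tok, ranked)
  expect_equal(cand$position, c(49, 60))
  expect_equal(cand$driving_feature, c("49-A", "60-E"))

  # an SM with no ranked feature sorts last
  tok[10] <- "W"
  cand <- rankSMCandidates(tok, ranked)
  expect_equal(cand$position, c(49, 60, 10))
  expect_equal(cand$best_rank[3], Inf)

  # pair features: best general rank wins
  ranked2 <- data.frame(name = c("49A-60E", "49-A"),
                        family = c("MAP", "AMP"),
                        pos1 = c(49, 49), pos2 = c(60, NA),
                        level = c("A-E", "A"),
                        general_rank = c(1, 5), stringsAsFactors = FALSE)
  tok <- rep("X", 80); tok[49] <- "A"; tok[60] <- "E"
  cand <- rankSMCandidates(tok, ranked2)
  expect_equal(cand$driving_feature[1], "49A-60E")
  expect_equal(cand$best_rank[1], 1)
})

test_that("a single planted toxic mutation is reverted in one step", {
  fx <- revert_fixture()
  gid <- "SYNV1*01:SYNJ1*01"
  uni <- fx$model$universe
  toxseq <- seq_with(fx$gl, gid, uni, list(`49` = "A"))
  plan <- greedyRevert(toxseq, gid, fx$gl, fx$model, fx$ranked)
  expect_equal(plan$final_label, "nox")
  expect_equal(nrow(plan$steps), 1)
  expect_equal(plan$steps$position, 49)
  expect_equal(plan$steps$from_aa, "A")
  expect_lt(plan$steps$confidence_after, plan$steps$confidence_before)
  # the final sequence is the germline restored at that position
  expect_equal(plan$final_sequence, glSequence(fx$gl, gid))
})

test_that("reversion steps restore only germline residues", {
  fx <- revert_fixture()
  gid <- "SYNV2*01:SYNJ2*01"
  uni <- fx$model$universe
  toxseq <- seq_with(fx$gl, gid, uni, list(`49` = "A", `60` = "E"))
  plan <- greedyRevert(toxseq, gid, fx$gl, fx$model, fx$ranked,
                       maxSteps = 10)
  if (nrow(plan$steps)) {
    glres <- strsplit(glSequence(fx$gl, gid), "")[[1]]
    posOf <- setNames(uni$position, uni$kc_label)
    pos_of_res <- posOf[glLabels(fx$gl, gid)]
    for (i in seq_len(nrow(plan$steps))) {
      ridx <- which(pos_of_res == plan$steps$position[i])
      expect_equal(plan$steps$to_germline_aa[i], glres[ridx])
    }
    # applying all steps leaves only un-reverted mutations
    fin <- strsplit(plan$final_sequence, "")[[1]]
    orig <- strsplit(toxseq, "")[[1]]
    changed <- which(fin != orig)
    expect_setequal(pos_of_res[changed],
                    plan$steps$position)
  }
})

test_that("a sequence predicted non-toxic yields a no-op plan", {
  fx <- revert_fixture()
  gid <- "SYNV1*01:SYNJ1*01"
  plan <- greedyRevert(glSequence(fx$gl, gid), gid, fx$gl, fx$model,
                       fx$ranked)
  expect_equal(nrow(plan$steps), 0)
  expect_false(plan$exhausted)
  expect_equal(plan$final_sequence, glSequence(fx$gl, gid))
})

test_that("reverting every somatic mutation converges to the germline call", {
  fx <- revert_fixture()
  gid <- "SYNV1*01:SYNJ1*01"
  uni <- fx$model$universe
  toxseq <- seq_with(fx$gl, gid, uni, list(`49` = "A", `55` = "W"))
  plan <- greedyRevert(toxseq, gid, fx$gl, fx$model, fx$ranked)
  gl_pred <- predictToxicity(fx$model,
                             encodeSequenceTokens(glSequence(fx$gl, gid),
                                                  gid, fx$gl, uni),
                             germlineIds = gid)
  if (plan$exhausted || plan$final_sequence == glSequence(fx$gl, gid)) {
    expect_equal(plan$final_label, gl_pred$label)
  }
  # removing planted signal never raises the toxicity confidence above start
  first_conf <- if (nrow(plan$steps)) plan$steps$confidence_before[1] else
    plan$final_confidence
  expect_lte(plan$final_confidence, first_conf + 1e-9)
})
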