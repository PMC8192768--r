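# Synthetic repertoire generator and toy structure.

test_that("generation is a pure function of the spec", {
  spec <- simSpec(nTox = 15, nNox = 15, backgroundRate = 0.05, seed = 77)
  r1 <- generateRepertoire(spec)
  r2 <- generateRepertoire(spec)
  expect_identical(r1$records, r2$records)
  # and the global RNG stream is untouched
  withr::with_seed(1, {
    x <- runif(1)
    set.seed(1); invisible(generateRepertoire(spec)); y <- runif(1)
    expect_equal(x, y)
  })
})

test_that("empty and contradictory specs are handled", {
  spec <- simSpec(nTox = 0, nNox = 0)
  expect_equal(nrow(generateRepertoire(spec)$records), 0)

  expect_error(simSpec(backgroundRate = 1.2), "\\[0, 1\\]")
  expect_error(
    simSpec(plantedEffects = data.frame(position = 40, aa = "W",
                                        p_tox = 0.5, p_nox = 0.1)),
    "contradictory")
  expect_error(
    simSpec(plantedEffects = data.frame(position = 9999, aa = "E",
                                        p_tox = 0.5, p_nox = 0.1)),
    "universe")
})

test_that("planted effect frequencies concentrate at their class rates", {
  ## no background, one planted effect: carrier frequencies must sit within
  ## 3-sigma binomial bands of the class-conditional probabilities
  n <- 3000
  spec <- simSpec(nTox = n, nNox = n, backgroundRate = 0,
                  plantedEffects = data.frame(position = 49, aa = "A",
                                              p_tox = 0.5, p_nox = 0.02),
                  seed = 123)
  sim <- generateRepertoire(spec)
  tr <- sim$truth$planted
  band <- function(p) 3 * sqrt(p * (1 - p) / n)
  expect_lt(abs(tr$n_tox / n - 0.5), band(0.5))
  expect_lt(abs(tr$n_nox / n - 0.02), band(0.02))
  # with zero background, every mutation is the planted one
  sme <- encodeDataset(sim$records[seq(1, 2 * n, by = 10), ],
                       sim$germlines)
  expect_true(all(nSM(sme) <= 1))
})

test_that("null data produce calibrated Fisher rejections and null AUC", {
  spec <- simSpec(nTox = 250, nNox = 250, backgroundRate = 0.03, seed = 55)
  sme <- encodeDataset(generateRepertoire(spec)$records, spec$germlines)
  st <- positionStats(sme)
  frac <- mean(st$p < 0.05)
  ## the exact test is conservative, so the rejection fraction must not
  ## exceed the nominal level by more than 3 binomial sigmas (it may be far
  ## below it)
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / nrow(st)))
})

test_that("toy structures realize the requested contact pattern", {
  ts <- generateToyStructure(1:8, interfacePositions = c(2, 6),
                             monomericPairs = rbind(c(3, 4)))
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(ts$pdb, f)
  co <- loadStructureCbeta(f, c("A", "B"))   # re-parses without error
  cm <- buildContactMap(co$A, co$B, ts$map)
  expect_equal(unname(dimericPairs(cm)), rbind(c(2L, 2L), c(6L, 6L)))
  expect_equal(unname(monomericPairs(cm)), rbind(c(3L, 4L)))

  # no interface positions -> empty dimeric set
  ts0 <- generateToyStructure(1:5)
  writeLines(ts0$pdb, f)
  co0 <- loadStructureCbeta(f, c("A", "B"))
  cm0 <- buildContactMap(co0$A, co0$B, ts0$map)
  expect_equal(nrow(dimericPairs(cm0)), 0)
  expect_equal(nrow(monomericPairs(cm0)), 0)

  expect_error(generateToyStructure(1:5, interfacePositions = 9),
               "subset")
  expect_error(generateToyStructure(1:6, interfacePositions = c(1, 2),
                                    monomericPairs = rbind(c(1, 2))),
               "infeasibility")
})

test_that("class-conditional germline usage is honoured", {
  gl <- toyGermlineSet()
  usage <- matrix(c(1, 0, 0, 0,
                    0, 1, 0, 0), 2, 4, byrow = TRUE,
                  dimnames = list(c("tox", "nox"), germlineIds(gl)))
  spec <- simSpec(nTox = 20, nNox = 20, backgroundRate = 0, usage = usage,
                  seed = 9)
  sim <- generateRepertoire(spec)
  expect_true(all(sim$records$germline_id[sim$records$label == "tox"] ==
                    germlineIds(gl)[1]))
  expect_true(all(sim$records$germline_id[sim$records$label == "nox"] ==
                    germlineIds(gl)[2]))
})
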