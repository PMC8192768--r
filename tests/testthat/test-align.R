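# Germline alignment, label transfer and progressive renumbering.

test_that("global alignment reproduces the worked example and identity cases", {
  ap <- globalAlign("SYELTQPP", "SYVLTQPP")
  expect_equal(ap$lcAligned, "SYELTQPP")
  expect_equal(ap$glAligned, "SYVLTQPP")
  expect_equal(ap$score, 7 * 1 + 1 * (-1))

  ap <- globalAlign("QSVLTQ", "QSVLTQ")
  expect_equal(ap$score, 6)
  expect_false(grepl("-", ap$lcAligned, fixed = TRUE))

  expect_error(globalAlign("", "A"), "non-empty")
})

test_that("alignment score equals exhaustive enumeration on small strings", {
  alphabet <- c("A", "C", "D")
  small <- unlist(lapply(1:3, function(n)
    apply(expand.grid(rep(list(alphabet), n)), 1, paste, collapse = "")))
  for (a in small[seq(1, length(small), by = 3)]) {
    for (b in small[seq(1, length(small), by = 4)]) {
      expect_equal(globalAlign(a, b)$score, enum_align_score(a, b),
                   info = paste(a, b))
    }
  }
  # random longer pairs (length 4-5)
  withr::with_seed(7, {
    for (k in 1:40) {
      a <- paste(sample(alphabet, sample(4:5, 1), TRUE), collapse = "")
      b <- paste(sample(alphabet, sample(4:5, 1), TRUE), collapse = "")
      expect_equal(globalAlign(a, b)$score, enum_align_score(a, b),
                   info = paste(a, b))
    }
  })
})

test_that("alignment invariants: gap removal recovers inputs, symmetric score", {
  withr::with_seed(11, {
    for (k in 1:25) {
      a <- paste(sample(c("A", "C", "D", "E"), sample(3:8, 1), TRUE),
                 collapse = "")
      b <- paste(sample(c("A", "C", "D", "E"), sample(3:8, 1), TRUE),
                 collapse = "")
      ap <- globalAlign(a, b)
      expect_equal(nchar(ap$lcAligned), nchar(ap$glAligned))
      expect_equal(gsub("-", "", ap$lcAligned, fixed = TRUE), a)
      expect_equal(gsub("-", "", ap$glAligned, fixed = TRUE), b)
      # no column with gaps in both rows
      la <- strsplit(ap$lcAligned, "")[[1]]
      ga <- strsplit(ap$glAligned, "")[[1]]
      expect_false(any(la == "-" & ga == "-"))
      # score symmetric under swap (scoring is symmetric)
      expect_equal(ap$score, globalAlign(b, a)$score)
    }
  })
})

test_that("numbering transfer inherits, inserts and skips labels correctly", {
  # gapless: labels identical to germline labels
  ap <- globalAlign("SYELTQ", "SYVLTQ")
  expect_identical(transferNumbering(ap, as.character(1:6)),
                   as.character(1:6))

  # one LC insertion after germline label 30 -> 30A
  ap <- list(lcAligned = "ACDEF", glAligned = "AC-EF")
  expect_identical(transferNumbering(ap, c("29", "30", "31", "32")),
                   c("29", "30", "30A", "31", "32"))

  # insertion after an existing insertion continues the letters
  ap <- list(lcAligned = "ACD", glAligned = "AC-")
  expect_identical(transferNumbering(ap, c("30", "30A")),
                   c("30", "30A", "30B"))

  # deletion: labeled positions are the germline labels minus the deleted one
  ap <- list(lcAligned = "AB-DEF", glAligned = "ABCDEF")
  labs <- transferNumbering(ap, as.character(1:6))
  expect_identical(labs, c("1", "2", "4", "5", "6"))

  # insertion-letter overflow
  ap <- list(lcAligned = "AB", glAligned = "A-")
  expect_error(transferNumbering(ap, "5Z"), "exhausted")
})

test_that("progressive renumbering is a dense monotone bijection", {
  # the CDR1 insertion worked example: 30A..30F occupy 31..36
  uni <- c(as.character(1:30), paste0("30", LETTERS[1:6]),
           as.character(31:40))
  m <- renumberProgressive(uni)
  expect_equal(unname(m[paste0("30", LETTERS[1:6])]), 31:36)
  expect_equal(unname(m["31"]), 37)

  # no insertion letters: identity on rank
  m <- renumberProgressive(as.character(5:1))
  expect_equal(unname(m[as.character(1:5)]), 1:5)

  # random universes: monotone and dense against a sort-based oracle
  withr::with_seed(3, {
    for (k in 1:20) {
      nums <- sample(1:60, sample(5:15, 1))
      labs <- unique(c(as.character(nums),
                       paste0(sample(nums, 3, TRUE),
                              sample(LETTERS[1:4], 3, TRUE))))
      m <- renumberProgressive(labs)
      expect_equal(sort(unname(m)), seq_along(labs))
      key <- order(match(names(m), kabatSort(labs)))
      expect_equal(unname(m[kabatSort(labs)]), seq_along(labs))
    }
  })

  expect_error(renumberProgressive(c("1", "2", "1")), "duplicate")
})
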