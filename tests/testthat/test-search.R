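# Ordering strategies, pair/tube predicates and the depth-first tiling
# search.

test_that("ordering strategies permute the canonical candidate order", {
  df <- data.frame(start = c(10, 40, 70), end = c(33, 63, 93))
  expect_identical(orderCandidates(df, "forward", "bothNormal")$start,
                   c(10, 40, 70))
  expect_identical(orderCandidates(df, "forward", "fwdReverse")$start,
                   c(70, 40, 10))
  expect_identical(orderCandidates(df, "reverse", "fwdReverse")$start,
                   c(10, 40, 70))
  expect_identical(orderCandidates(df, "reverse", "revReverse")$start,
                   c(70, 40, 10))
  expect_identical(orderCandidates(df, "forward", "bothReverse")$start,
                   c(70, 40, 10))
  expect_identical(nrow(orderCandidates(df[0, ], "forward", "bothNormal")), 0L)
  expect_error(orderCandidates(df, "forward", "sideways"),
               "bothNormal.*fwdReverse.*revReverse.*bothReverse")
})

test_that("pair validity enforces product length, Tm spread and heterodimer floor", {
  cfg <- quickConfig()
  mk <- function(start, end, seq, tm) {
    data.frame(start = start, end = end, sequence = seq, tmC = tm)
  }
  f <- mk(0L, 23L, "AGCGTAGCTAGCTAGCTAGCTAG", 60)
  r <- function(end, tm = 60) mk(end - 23L, end,
                                 "TCCATGACGTTACAGATGCATGC", tm)
  expect_false(pairIsValid(f, r(299L), cfg))
  expect_true(pairIsValid(f, r(300L), cfg))
  expect_true(pairIsValid(f, r(500L), cfg))
  expect_false(pairIsValid(f, r(501L), cfg))
  expect_false(pairIsValid(f, r(400L, tm = 60.6), cfg))
  expect_true(pairIsValid(f, r(400L, tm = 60.5), cfg))
  # a reverse primer that is the forward's reverse complement dimerizes
  expect_false(pairIsValid(f, mk(377L, 400L, revComp(f$sequence), 60), cfg))
})

test_that("tube compatibility is a vacuous-to-pairwise clique check", {
  cfg <- quickConfig()
  a <- "AGCGTAGCTAGCTAGCTAGCTAG"
  b <- "TCCATGACGTTACAGATGCATGC"
  expect_true(tubeCompatible(a, character(0), cfg))
  expect_false(tubeCompatible(a, c(b, revComp(a)), cfg))
  expect_false(tubeCompatible(a, c(revComp(a), b), cfg))  # order-independent
  expect_true(tubeCompatible(a, c(b), cfg))
})

test_that("the search recovers the unique tiling of a poison fixture", {
  cfg <- quickConfig(flank = 240)
  reg <- cachedFixture(42, length = 1600, flank = 240, poison = TRUE)
  tilings <- bruteForceTilings(reg, cfg)
  expect_length(tilings, 1L)
  sol <- designMultiplex(reg, cfg)
  expect_identical(solutionStatus(sol), "solved")
  expect_identical(solutionPairs(sol), solutionPairs(tilings[[1]]))
  expect_true(verifySolution(sol, reg, cfg))
  # round-robin tubes over two tubes alternate 0,1,0,1,...
  expect_identical(solutionPairs(sol)$tube,
                   (seq_len(nrow(solutionPairs(sol))) - 1L) %% 2L)
})

test_that("a zero budget times out before expanding any node", {
  cfg <- quickConfig(flank = 240)
  cfg@timeLimitS <- 0
  reg <- cachedFixture(42, length = 1600, flank = 240, poison = TRUE)
  sol <- designMultiplex(reg, cfg)
  expect_identical(solutionStatus(sol), "timeout")
  expect_identical(nrow(solutionPairs(sol)), 0L)
})

test_that("an empty first window is infeasible with a distinguishing diagnostic", {
  # poison fixture generated for flank 240 has no candidate before base 120
  reg <- cachedFixture(42, length = 1600, flank = 240, poison = TRUE)
  cfg <- quickConfig(flank = 120)
  sol <- designMultiplex(reg, cfg)
  expect_identical(solutionStatus(sol), "infeasible")
  expect_match(sol@diagnostic, "first boundary window")
})

test_that("a region too short for any amplicon is infeasible", {
  reg <- targetRegion("tiny", strrep("ACGT", 100), 120)  # 400 bases
  cfg <- quickConfig(flank = 120)
  sol <- designMultiplex(reg, cfg)
  expect_identical(solutionStatus(sol), "infeasible")
})

test_that("a single test tube is rejected at configuration time", {
  expect_error(designConfig(mTubes = 1L), "at least two test tubes")
})

test_that("the search is deterministic for fixed inputs", {
  cfg <- quickConfig()
  reg <- cachedFixture(7, length = 1300, flank = 120)
  s1 <- designMultiplex(reg, cfg)
  s2 <- designMultiplex(reg, cfg)
  expect_identical(solutionPairs(s1), solutionPairs(s2))
  expect_identical(solutionStatus(s1), solutionStatus(s2))
})

test_that("orderings steer the search to different first solutions", {
  # non-poison fixture with many interchangeable candidates
  reg <- cachedFixture(7, length = 1300, flank = 120)
  cfgN <- quickConfig(); cfgR <- quickConfig(ordering = "bothReverse")
  sN <- designMultiplex(reg, cfgN)
  sR <- designMultiplex(reg, cfgR)
  expect_identical(solutionStatus(sN), "solved")
  expect_identical(solutionStatus(sR), "solved")
  expect_false(identical(solutionPairs(sN), solutionPairs(sR)))
  expect_true(verifySolution(sN, reg, cfgN))
  expect_true(verifySolution(sR, reg, cfgR))
})

test_that("feasibility is monotone in the tube count on compatible fixtures", {
  reg <- cachedFixture(42, length = 1600, flank = 240, poison = TRUE)
  for (m in 2:4) {
    cfg <- quickConfig(flank = 240, mTubes = m)
    expect_identical(solutionStatus(designMultiplex(reg, cfg)), "solved")
    expect_gte(length(bruteForceTilings(reg, cfg)), 1L)
  }
})
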