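# Synthetic-region generator and the exhaustive tiling enumerator.

test_that("fixture generation is seed-deterministic", {
  cfg <- designConfig(flankLen = 120L)
  a <- generateRegion(fixtureSpec(length = 1300, seed = 7), cfg)
  b <- generateRegion(fixtureSpec(length = 1300, seed = 7), cfg)
  expect_identical(regionSequence(a), regionSequence(b))
  expect_identical(variantPositions(a), variantPositions(b))
  c <- generateRegion(fixtureSpec(length = 1300, seed = 8), cfg)
  expect_false(identical(regionSequence(a), regionSequence(c)))
})

test_that("fixture generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(cachedFixture(7, length = 1300, flank = 120))
  expect_identical(.Random.seed, before)
})

test_that("planted windows yield their candidates and a feasible tiling", {
  cfg <- quickConfig()
  reg <- cachedFixture(7, length = 1300, flank = 120)
  md <- reg@metadata
  for (i in seq_along(md$fwdStart)) {
    fw <- enumerateCandidates(reg, md$fwdStart[i], md$fwdStart[i] + 1L,
                              "forward", cfg)
    expect_true(md$fwdOligo[i] %in% fw$sequence)
    rv <- enumerateCandidates(reg, md$revEnd[i] - 1L, md$revEnd[i],
                              "reverse", cfg)
    expect_true(md$revOligo[i] %in% rv$sequence)
  }
  expect_identical(solutionStatus(designMultiplex(reg, cfg)), "solved")
})

test_that("variant planting respects the requested density and footprints", {
  cfg <- designConfig(flankLen = 120L)
  none <- generateRegion(fixtureSpec(length = 1300, seed = 5,
                                     variantDensity = 0), cfg)
  expect_identical(variantPositions(none), integer(0))
  some <- generateRegion(fixtureSpec(length = 1300, seed = 5,
                                     variantDensity = 10), cfg)
  expect_identical(length(variantPositions(some)), 13L)  # 10/kb * 1.3 kb
  md <- some@metadata
  footprints <- unlist(lapply(seq_along(md$fwdStart), function(i) {
    c(md$fwdStart[i]:(md$fwdStart[i] + 22L),
      (md$revEnd[i] - 23L):(md$revEnd[i] - 1L))
  }))
  expect_false(any(variantPositions(some) %in% footprints))
})

test_that("poison fixtures admit exactly one tiling, found by the search", {
  cfg <- quickConfig(flank = 240)
  reg <- cachedFixture(42, length = 1600, flank = 240, poison = TRUE)
  tilings <- bruteForceTilings(reg, cfg)
  expect_length(tilings, 1L)
  expect_true(verifySolution(tilings[[1]], reg, cfg))
  sol <- designMultiplex(reg, cfg)
  expect_identical(solutionPairs(sol), solutionPairs(tilings[[1]]))
})

test_that("the enumerator guard refuses oversized candidate sets", {
  cfg <- quickConfig()
  reg <- cachedFixture(7, length = 1300, flank = 120)
  expect_error(bruteForceTilings(reg, cfg, maxCandidates = 3L),
               "shrink the fixture")
})

test_that("a fixture with its first planted site destroyed has no tiling", {
  cfg <- quickConfig(flank = 240)
  reg <- cachedFixture(42, length = 1600, flank = 240, poison = TRUE)
  md <- reg@metadata
  seq <- regionSequence(reg)
  s <- md$fwdStart[1]
  substr(seq, s + 1, s + 23) <- strrep("A", 23)
  broken <- targetRegion("broken", seq, 240)
  expect_length(bruteForceTilings(broken, cfg), 0L)
  sol <- designMultiplex(broken, cfg)
  expect_identical(solutionStatus(sol), "infeasible")
})
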