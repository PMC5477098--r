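# Oligo-level physical quantities: GC, homopolymer runs, nearest-neighbor
# Tm and duplex/hairpin free energies.

test_that("gcFraction is the exact G+C count over length", {
  expect_equal(gcFraction("AAAA"), 0)
  expect_equal(gcFraction("GCGC"), 1)
  expect_equal(gcFraction("ATGC"), 0.5)
  expect_error(gcFraction(character(0)), "non-empty")
  expect_error(gcFraction("ACGN"), "A/C/G/T")
})

test_that("maxHomopolymerRun finds the longest single-base run", {
  expect_equal(maxHomopolymerRun("ACGT"), 1L)
  expect_equal(maxHomopolymerRun("AAAT"), 3L)
  expect_equal(maxHomopolymerRun("CGGGGA"), 4L)
  expect_error(maxHomopolymerRun(""), "non-empty")
})

test_that("GC and run statistics are invariant under reversal and base-swap", {
  set.seed(41)
  for (o in randomOligo(25, 24)) {
    revd <- paste(rev(strsplit(o, "")[[1]]), collapse = "")
    swapped <- chartr("ACGT", "TGCA", o)
    expect_identical(maxHomopolymerRun(o), maxHomopolymerRun(revd))
    expect_equal(gcFraction(o), gcFraction(revd))
    expect_equal(gcFraction(o), gcFraction(swapped))
  }
})

test_that("melting temperature matches an independently summed NN oracle", {
  p23 <- "AGCGTAGCTAGCTAGCTAGCTAG"
  expect_equal(meltingTemperature(p23), oracleTm(p23), tolerance = 1e-9)
  expect_equal(meltingTemperature(p23), 60.9233, tolerance = 1e-3)
  # repeatability
  expect_identical(meltingTemperature(p23), meltingTemperature(p23))
  set.seed(7)
  for (o in randomOligo(30, sample(18:28, 1))) {
    expect_equal(meltingTemperature(o), oracleTm(o), tolerance = 1e-9)
  }
})

test_that("raising GC by an A->G substitution raises Tm", {
  base <- "AGCGTAGCTAGCTAGCTAGCTAG"
  sub <- sub("A", "G", base)   # first A -> G
  expect_gt(meltingTemperature(sub), meltingTemperature(base))
  expect_gt(oracleTm(sub), oracleTm(base))
})

test_that("Tm responds to solution conditions and rejects short oligos", {
  p <- "AGCGTAGCTAGCTAGCTAGCTAG"
  lowSalt <- thermoConfig(monovalentmM = 10, divalentmM = 0)
  expect_lt(meltingTemperature(p, lowSalt), meltingTemperature(p))
  expect_error(meltingTemperature("ACGTACG"), "at least 8")
})

test_that("duplexDG matches exhaustive alignment enumeration on random oligos", {
  set.seed(11)
  for (i in 1:60) {
    a <- randomOligo(1, sample(8:12, 1))
    b <- randomOligo(1, sample(8:12, 1))
    expect_equal(duplexDG(a, b), oracleDuplexDG(a, b), tolerance = 1e-9,
                 info = paste(a, b))
  }
})

test_that("duplexDG handles the canonical cases", {
  p <- "AGCGTAGCTAGCTAGCTAGCTAG"
  expect_lt(duplexDG(p, revComp(p)), -20)        # perfect 23-bp duplex
  polyA <- strrep("A", 12)
  expect_identical(duplexDG(polyA, polyA), 0)    # A.A never pairs
  set.seed(13)
  for (i in 1:40) {
    a <- randomOligo(1, 10); b <- randomOligo(1, 10)
    expect_identical(duplexDG(a, b), duplexDG(b, a))
  }
})

test_that("extending a perfect duplex never weakens it", {
  set.seed(17)
  for (i in 1:20) {
    a <- randomOligo(1, sample(10:20, 1))
    ext <- paste0(a, sample(c("A", "C", "G", "T"), 1))
    expect_lte(duplexDG(ext, revComp(ext)), duplexDG(a, revComp(a)))
  }
})

test_that("hairpinDG matches exhaustive stem-loop enumeration", {
  expect_lt(hairpinDG("GGGGAAAACCCC"), 0)
  expect_identical(hairpinDG("ATATATAT"), 0)
  set.seed(19)
  for (i in 1:60) {
    s <- randomOligo(1, sample(8:12, 1))
    expect_equal(hairpinDG(s), oracleHairpinDG(s), tolerance = 1e-9, info = s)
  }
})

test_that("hairpinDG never reports a favorable score above zero", {
  set.seed(23)
  for (s in randomOligo(40, 15)) expect_lte(hairpinDG(s), 0)
})
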