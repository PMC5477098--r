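# Candidate enumeration against an independently coded screening predicate,
# plus the specificity filter.

test_that("enumeration agrees with the brute-force predicate on a fixture window", {
  reg <- cachedFixture(31, length = 1300, flank = 120)
  cfg <- quickConfig()
  for (strand in c("forward", "reverse")) {
    got <- enumerateCandidates(reg, 200, 320, strand, cfg)
    # independent double loop over every (anchor, length)
    want <- list()
    for (anchor in 200:319) {
      for (L in 23:30) {
        if (strand == "forward") { s <- anchor; e <- s + L }
        else { e <- anchor + 1; s <- e - L }
        if (s < 0 || e > regionLength(reg)) next
        tmpl <- substr(regionSequence(reg), s + 1, e)
        oligo <- if (strand == "reverse") oracleRevComp(tmpl) else tmpl
        if (oraclePrimerOK(oligo, s, e, strand, regionSequence(reg),
                           variantPositions(reg), cfg@optimumTmC))
          want[[length(want) + 1]] <- c(s, e)
      }
    }
    wantMat <- if (length(want)) do.call(rbind, want) else matrix(0L, 0, 2)
    expect_identical(nrow(got), nrow(wantMat))
    if (nrow(got)) {
      ord <- order(wantMat[, 1], wantMat[, 2])
      expect_identical(got$start, as.integer(wantMat[ord, 1]))
      expect_identical(got$end, as.integer(wantMat[ord, 2]))
    }
  }
})

test_that("every returned candidate satisfies every screening invariant", {
  reg <- cachedFixture(31, length = 1300, flank = 120)
  cfg <- quickConfig()
  cands <- enumerateCandidates(reg, 0, regionLength(reg), "forward", cfg)
  expect_gt(nrow(cands), 0)
  expect_true(all(cands$end - cands$start >= 23 & cands$end - cands$start <= 30))
  expect_true(all(cands$gc >= 0.30 & cands$gc <= 0.70))
  expect_true(all(maxHomopolymerRun(cands$sequence) <= 3))
  expect_true(all(abs(cands$tmC - cfg@optimumTmC) <= 0.5))
  expect_true(all(cands$hairpinDG >= -3 & cands$homodimerDG >= -3))
  # canonical order: ascending start, ties by ascending length
  expect_true(all(diff(cands$start) >= 0))
  o <- order(cands$start, cands$end - cands$start)
  expect_identical(o, seq_len(nrow(cands)))
})

test_that("a high-GC 23-mer is excluded by the GC ceiling", {
  # engineered window: 23-mer with 18 G/C (GC = 0.78) embedded in A/T filler
  core <- paste0("GCGCGCGCATGCGCGCGCATGCG")
  seq <- paste0(strrep("ATTA", 40), core, strrep("TAAT", 200))
  reg <- targetRegion("gcHigh", seq, 120)
  cfg <- quickConfig()
  got <- enumerateCandidates(reg, 160, 161, "forward", cfg)
  expect_false(any(got$start == 160 & got$end == 183))
})

test_that("a window inside a poly-A tract yields nothing", {
  seq <- paste0(strrep("ACGT", 50), strrep("A", 100), strrep("ACGT", 100))
  reg <- targetRegion("polyA", seq, 120)
  got <- enumerateCandidates(reg, 210, 260, "forward", quickConfig())
  expect_identical(nrow(got), 0L)
})

test_that("a variant under the 3' terminal three bases disqualifies a candidate", {
  reg0 <- cachedFixture(31, length = 1300, flank = 120)
  cfg <- quickConfig()
  all0 <- enumerateCandidates(reg0, 0, regionLength(reg0), "forward", cfg)
  expect_gt(nrow(all0), 0)
  pick <- all0[1, ]
  # plant a variant under the last base: candidate disappears
  regHit <- targetRegion(regionName(reg0), regionSequence(reg0), 120,
                         variantPositions = pick$end - 1L)
  gotHit <- enumerateCandidates(regHit, pick$start, pick$start + 1L,
                                "forward", cfg)
  expect_false(any(gotHit$end == pick$end))
  # same variant four bases in from the 3' end: candidate survives
  regMiss <- targetRegion(regionName(reg0), regionSequence(reg0), 120,
                          variantPositions = pick$end - 4L)
  gotMiss <- enumerateCandidates(regMiss, pick$start, pick$start + 1L,
                                 "forward", cfg)
  expect_true(any(gotMiss$end == pick$end))
})

test_that("enumeration is a pure function of its inputs", {
  reg <- cachedFixture(31, length = 1300, flank = 120)
  cfg <- quickConfig()
  a <- enumerateCandidates(reg, 0, 400, "reverse", cfg)
  b <- enumerateCandidates(reg, 0, 400, "reverse", cfg)
  expect_identical(a, b)
  expect_identical(nrow(enumerateCandidates(reg, 200, 200, "forward", cfg)), 0L)
})

test_that("exact-match specificity keeps self-hits and drops duplicated oligos", {
  reg <- cachedFixture(31, length = 1300, flank = 120)
  cfg <- quickConfig()
  cands <- head(enumerateCandidates(reg, 0, regionLength(reg), "forward", cfg), 4)
  expect_gt(nrow(cands), 0)
  # reference = the region itself: every candidate occurs exactly once
  be1 <- exactMatchBackend(regionSequence(reg))
  kept <- applySpecificityFilter(cands, be1)
  expect_identical(kept$sequence, cands$sequence)
  expect_true(all(kept$specificityChecked))
  # duplicate one candidate elsewhere in the reference: it is discarded
  dupRef <- paste0(regionSequence(reg), strrep("T", 30), cands$sequence[1])
  be2 <- exactMatchBackend(dupRef)
  kept2 <- applySpecificityFilter(cands, be2)
  expect_false(cands$sequence[1] %in% kept2$sequence)
  expect_identical(nrow(kept2), nrow(cands) - 1L)
  # a reverse-complement occurrence counts as a binding site too
  rcRef <- paste0(regionSequence(reg), strrep("T", 30), revComp(cands$sequence[2]))
  expect_identical(querySpecificity(exactMatchBackend(rcRef),
                                    cands$sequence[2]), 2L)
  # identity on the empty list
  empty <- cands[0, ]
  expect_identical(nrow(applySpecificityFilter(empty, be1)), 0L)
})

test_that("the blastn backend counts sub-threshold alignments", {
  reg <- cachedFixture(31, length = 1300, flank = 120)
  cfg <- quickConfig()
  cand <- enumerateCandidates(reg, 0, regionLength(reg), "forward", cfg)[1, ]
  db <- tempfile()
  fa <- paste0(db, ".fa")
  writeLines(c(">ref", regionSequence(reg)), fa)
  ok <- system2("makeblastdb",
                c("-in", fa, "-dbtype", "nucl", "-out", db),
                stdout = FALSE, stderr = FALSE)
  expect_identical(ok, 0L)
  be <- blastBackend(db)
  expect_identical(querySpecificity(be, cand$sequence), 1L)
  kept <- applySpecificityFilter(cand, be)
  expect_identical(nrow(kept), 1L)
  expect_true(kept$specificityChecked)
})
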